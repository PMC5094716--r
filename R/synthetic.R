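# Synthetic two-body membrane ensembles with exact ground truth.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes -- many independent association runs of two rigid receptors in a
# flat two-leaflet bilayer -- not the physics that produces it. Binding and
# unbinding are stochastic two-state events with geometric placement at
# planted (beta, chi) dimer modes; lateral motion is Brownian with
# configured diffusion coefficients; cholesterol hotspot contacts follow a
# two-state Markov chain with a planted stationary occupancy.

#' Configuration for the synthetic ensemble generator
#'
#' Defaults reproduce the pure-POPC study conditions: 500 independent runs
#' of 3 us, receptors initially separated by a 3.5 nm circumscribed-sphere
#' gap with uniform random z-rotations, an ensemble first-order association
#' constant of 0.274e6 s^-1 (2.74e-4 ns^-1), a dissociation rate giving an
#' equilibrium post-dissociation monomer/dimer time ratio of about 0.031,
#' five dimer modes at helix-interface angles with weights
#' (0.26, 0.24, 0.20, 0.13, 0.17), and Table-4-level diffusion
#' coefficients.
#'
#' @param n_runs number of independent runs.
#' @param run_length run length in ns.
#' @param frame_stride frame spacing in ns.
#' @param box rectangular box `c(Lx, Ly, Lz)` in nm.
#' @param association_rate ensemble first-order binding hazard, ns^-1. The
#'   binding hazard is homogeneous in time, so this rate is identically the
#'   analytic first-order rate constant of the monomer decay.
#' @param dissociation_rate unbinding hazard while bound, ns^-1.
#' @param dimer_modes data.frame with columns `name`, `beta`, `chi`
#'   (degrees), `weight` (summing to 1) and `spread` (wrapped-normal
#'   angular jitter sd, degrees).
#' @param D_protein,D_popc,D_chol lateral diffusion coefficients, cm^2/s.
#' @param cholesterol_fraction fraction of lipids that are cholesterol.
#' @param hotspot list with `residues` (residue numbers on protein A, one
#'   constrained cholesterol each), `occupancy` (target stationary contact
#'   fraction) and `mean_contact` (mean contact duration, ns).
#' @param helix_ranges template helix residue intervals.
#' @param template_radius,template_height template ring geometry, nm.
#' @param bilayer_thickness leaflet phosphate-to-phosphate distance, nm.
#' @param area_per_lipid lateral area per lipid, nm^2.
#' @param z_jitter Gaussian z-jitter of lipid reference beads, nm.
#' @param include_lipids generate membrane beads (disable for
#'   protein-kinetics-only ensembles).
#' @param n_intercalated number of cholesterols planted at the dimer
#'   interface while bound (0, 1 or 2).
#' @param bound_energy_target reference bound-configuration interaction
#'   energy the bead parameters are calibrated to, kJ/mol.
#' @param contact_gap closest bead-pair distance of a freshly placed dimer,
#'   nm.
#' @param unbind_gap circumscribed-sphere gap imposed on dissociation, nm.
#' @param initial_gap circumscribed-sphere gap of the initial placement, nm.
#' @param seed integer master seed; each run uses an independent stream
#'   derived from `(seed, run_id)`.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_runs = 500L,
                             run_length = 3000,
                             frame_stride = 1,
                             box = c(15, 15, 9),
                             association_rate = 2.74e-4,
                             dissociation_rate = 8.47e-6,
                             dimer_modes = default_dimer_modes(),
                             D_protein = 0.44e-7,
                             D_popc = 3.94e-7,
                             D_chol = 4.15e-7,
                             cholesterol_fraction = 0,
                             hotspot = list(residues = 50L, occupancy = 0.65,
                                            mean_contact = 6),
                             helix_ranges = cxcr4_helix_ranges(),
                             template_radius = 1.2,
                             template_height = 3.0,
                             bilayer_thickness = 4.2,
                             area_per_lipid = 0.64,
                             z_jitter = 0.1,
                             include_lipids = TRUE,
                             n_intercalated = 0L,
                             bound_energy_target = -150,
                             contact_gap = 0.5,
                             unbind_gap = 1.6,
                             initial_gap = 3.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$dimer_modes$weight) - 1) > 1e-8)
    stop("dimer mode weights must sum to 1")
  if (cfg$association_rate < 0 || cfg$dissociation_rate < 0)
    stop("rates must be >= 0")
  if (cfg$cholesterol_fraction < 0 || cfg$cholesterol_fraction > 1)
    stop("cholesterol_fraction must lie in [0, 1]")
  if (any(cfg$box <= 0)) stop("box lengths must be > 0")
  if (cfg$frame_stride <= 0 || cfg$run_length < cfg$frame_stride)
    stop("invalid run_length/frame_stride")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default planted dimer modes
#'
#' Five modes at the template's helix-interface angles: the compact
#' TM1/TM5-7 dimer, the TM1/TM5 dimer, the loose TM5/TM5 dimer, the
#' symmetric TM1/TM1 dimer, and the symmetric TM3,4/TM3,4 dimer, with
#' relative weights 0.26/0.24/0.20/0.13/0.17.
#'
#' @return data.frame with columns `name`, `beta`, `chi`, `weight`,
#'   `spread`.
#' @export
default_dimer_modes <- function() {
  sc <- helix_sector_centers()
  b34 <- wrap360((sc[["TM3"]] + sc[["TM4"]]) / 2)     # TM3/TM4 boundary
  data.frame(
    name = c("TM1/TM5-7", "TM1/TM5", "TM5/TM5", "TM1/TM1", "TM3,4/TM3,4"),
    beta = c(sc[["TM1"]], sc[["TM1"]], sc[["TM5"]], sc[["TM1"]], b34),
    chi = c(sc[["TM6"]], sc[["TM5"]], sc[["TM5"]], sc[["TM1"]], b34),
    weight = c(0.26, 0.24, 0.20, 0.13, 0.17),
    spread = 7,
    stringsAsFactors = FALSE)
}

# Per-run reproducible stream seed derived from (seed, run_id); kept below
# 2^31.
run_seed <- function(seed, run_id) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(run_id) * 7919) %%
               2147483647)
}

# Cholesterol bead z-offsets (nm) relative to the bilayer midplane for one
# leaflet; ROH (hydroxyl head) sits closest to the phosphate plane.
chol_z_offsets <- function(thickness, leaflet = 1) {
  leaflet * (thickness / 2 - 0.4 - 0.2 * (0:7))
}

#' Build the topology of a synthetic two-receptor system
#'
#' Two receptor templates (molecules 1 and 2), POPC represented by its PO4
#' reference bead, cholesterol by an 8-bead rod with the ROH head bead, and
#' a single Lennard-Jones bead type calibrated so that the reference
#' face-to-face contact configuration evaluates to
#' `config$bound_energy_target` (which guarantees bound frames classify far
#' below the -50 kJ/mol criterion and fully separated frames at exactly 0).
#'
#' @param config a `synthetic_config`.
#' @return a `cg_topology` with extra fields `template` (the
#'   `cg_template`), `n_popc`, `n_chol` and `d_ref` (reference contact
#'   center distance, nm).
#' @export
synthetic_topology <- function(config) {
  tmpl <- build_protein_template(config$helix_ranges, config$template_radius,
                                 config$template_height)
  nres <- nrow(tmpl$coords)
  prot <- function(mol) {
    data.frame(bead_id = NA_integer_, bead_name = "BB",
               residue_number = tmpl$residue_number,
               residue_name = tmpl$helix,
               molecule_id = mol, species = "protein",
               type_key = "BB", charge = 0, stringsAsFactors = FALSE)
  }
  beads <- rbind(prot(1L), prot(2L))

  n_popc <- 0L; n_chol <- 0L
  if (config$include_lipids) {
    free_area <- config$box[1] * config$box[2] -
      2 * pi * config$template_radius^2
    per_leaflet <- max(0L, floor(free_area / config$area_per_lipid))
    total <- 2L * per_leaflet
    n_chol <- as.integer(round(config$cholesterol_fraction * total))
    n_chol <- 2L * (n_chol %/% 2L)          # even split across leaflets
    n_popc <- as.integer(total - n_chol)
    mol <- 2L
    if (n_popc > 0) {
      mol_ids <- mol + seq_len(n_popc)
      beads <- rbind(beads, data.frame(
        bead_id = NA_integer_, bead_name = "PO4",
        residue_number = seq_len(n_popc), residue_name = "POPC",
        molecule_id = mol_ids, species = "POPC",
        type_key = "P4", charge = 0, stringsAsFactors = FALSE))
      mol <- mol + n_popc
    }
    if (n_chol > 0) {
      mol_ids <- rep(mol + seq_len(n_chol), each = 8L)
      beads <- rbind(beads, data.frame(
        bead_id = NA_integer_,
        bead_name = rep(c("ROH", paste0("C", 1:7)), n_chol),
        residue_number = rep(seq_len(n_chol), each = 8L),
        residue_name = "CHOL",
        molecule_id = mol_ids, species = "CHOL",
        type_key = "SC1", charge = 0, stringsAsFactors = FALSE))
    }
  }
  beads$bead_id <- seq_len(nrow(beads))

  # baseline single LJ type: well depth 3 kJ/mol at r_min = 0.5 nm
  eps <- 3; sigma <- 0.5 / 2^(1 / 6)
  types <- unique(beads$type_key)
  grid <- expand.grid(type_i = types, type_j = types,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$type_i <= grid$type_j, ]
  nb <- data.frame(grid, C6 = 4 * eps * sigma^6, C12 = 4 * eps * sigma^12)

  topo <- topology(beads, config$helix_ranges, nb)
  topo$template <- tmpl
  topo$n_popc <- n_popc
  topo$n_chol <- n_chol

  # calibrate the energy scale on the reference face-to-face contact
  d_ref <- contact_distance(tmpl, 0, 0, config$contact_gap)
  A <- place_template(tmpl, c(0, 0), 0)
  B <- place_template(tmpl, c(d_ref, 0), 180)
  np <- nrow(tmpl$coords)
  fr <- trajectory_frame(0, rbind(A, B), pmax(config$box, 4 * d_ref))
  e_ref <- pair_energy(fr, seq_len(np), np + seq_len(np), topo)
  if (e_ref >= 0) stop("reference contact configuration is not attractive")
  s <- config$bound_energy_target / e_ref
  topo$nonbonded$C6 <- topo$nonbonded$C6 * s
  topo$nonbonded$C12 <- topo$nonbonded$C12 * s
  topo$d_ref <- d_ref
  topo
}

#' Draw the initial placement of the two receptors
#'
#' Receptor A is placed uniformly in the box; receptor B at a uniform
#' random direction with the circumscribed-sphere gap equal to
#' `config$initial_gap` (the placement-protocol separation). Both receive
#' independent uniform z-rotations.
#'
#' @param config a `synthetic_config`.
#' @param template the receptor `cg_template`.
#' @return list with `posA`, `posB` (xy, nm), `zrotA`, `zrotB` (degrees)
#'   and `d0` (center distance, nm).
#' @export
generate_initial_placement <- function(config, template) {
  d0 <- 2 * template$r_circ + config$initial_gap
  if (d0 > min(config$box[1:2]) / 2)
    stop(sprintf(
      "box too small: initial center distance %.2f nm exceeds half the box",
      d0))
  posA <- stats::runif(2) * config$box[1:2]
  th <- stats::runif(1) * 2 * pi
  posB <- posA + d0 * c(cos(th), sin(th))
  list(posA = posA, posB = posB,
       zrotA = stats::runif(1) * 360, zrotB = stats::runif(1) * 360,
       d0 = d0)
}

#' Simulate one synthetic run
#'
#' Two-state binding/unbinding kinetics with geometric dimer placement,
#' Brownian lateral diffusion, a flat two-leaflet membrane, optional
#' hotspot-constrained and interface-intercalated cholesterols. All
#' randomness comes from a per-run stream derived from
#' `(config$seed, run_id)`, so runs are independently reproducible.
#'
#' @param config a `synthetic_config`.
#' @param run_id integer run identifier.
#' @param topo topology from [synthetic_topology()] (built once per
#'   ensemble and shared across runs).
#' @return list with `run` (a `cg_run`) and `truth` (ground-truth record:
#'   events, per-frame mode labels, first binding time, planted D values,
#'   hotspot occupancy realized/planted).
#' @export
simulate_run <- function(config, run_id, topo = synthetic_topology(config)) {
  set.seed(run_seed(config$seed, run_id))
  tmpl <- topo$template
  dt <- config$frame_stride
  n_frames <- as.integer(round(config$run_length / dt)) + 1L
  times <- (seq_len(n_frames) - 1) * dt
  box <- config$box
  modes <- config$dimer_modes

  p_bind <- 1 - exp(-config$association_rate * dt)
  p_unbind <- 1 - exp(-config$dissociation_rate * dt)
  sd_prot <- sqrt(2 * config$D_protein * 1e5 * dt)   # cm^2/s -> nm^2/ns

  init <- generate_initial_placement(config, tmpl)
  posA <- matrix(NA_real_, n_frames, 2)
  posB <- matrix(NA_real_, n_frames, 2)
  zrotB <- numeric(n_frames)
  bound <- logical(n_frames)
  mode_id <- integer(n_frames)
  beta_f <- rep(NA_real_, n_frames)
  chi_f <- rep(NA_real_, n_frames)
  posA[1, ] <- init$posA; posB[1, ] <- init$posB
  zrotA <- init$zrotA; zrotB[1] <- init$zrotB

  events <- list()
  cur_bound <- FALSE; cur_mode <- 0L
  for (j in 2:n_frames) {
    posA[j, ] <- posA[j - 1, ] + stats::rnorm(2, 0, sd_prot)
    if (!cur_bound) {
      posB[j, ] <- posB[j - 1, ] + stats::rnorm(2, 0, sd_prot)
      # hard-core exclusion: free receptors never overlap, so unbound
      # frames sit strictly outside the interaction cutoff (E = 0)
      excl_AB <- 2 * config$template_radius + 1.25
      posB[j, ] <- drop(push_out(matrix(posB[j, ], 1), posA[j, ],
                                 excl_AB, box))
      zrotB[j] <- zrotB[j - 1]
      if (stats::runif(1) < p_bind) {
        cur_bound <- TRUE
        cur_mode <- sample.int(nrow(modes), 1, prob = modes$weight)
        events[[length(events) + 1L]] <-
          data.frame(time = times[j], type = "bind",
                     mode = modes$name[cur_mode])
      }
    } else if (stats::runif(1) < p_unbind) {
      cur_bound <- FALSE
      events[[length(events) + 1L]] <-
        data.frame(time = times[j], type = "unbind",
                   mode = modes$name[cur_mode])
      cur_mode <- 0L
      th <- stats::runif(1) * 2 * pi
      dsep <- 2 * tmpl$r_circ + config$unbind_gap
      posB[j, ] <- posA[j, ] + dsep * c(cos(th), sin(th))
      zrotB[j] <- stats::runif(1) * 360
    }
    if (cur_bound) {
      sp <- modes$spread[cur_mode]
      b <- wrap360(modes$beta[cur_mode] + stats::rnorm(1, 0, sp))
      x <- wrap360(modes$chi[cur_mode] + stats::rnorm(1, 0, sp))
      phi <- wrap360(180 + b - x)
      # center distance re-solved per frame so the closest bead pair sits
      # at the contact gap whatever the jittered interface orientation
      d <- contact_distance(tmpl, b, x, config$contact_gap)
      ang <- (zrotA + b) * pi / 180
      posB[j, ] <- posA[j, ] + d * c(cos(ang), sin(ang))
      zrotB[j] <- wrap360(zrotA + phi)
      beta_f[j] <- b; chi_f[j] <- x
    }
    bound[j] <- cur_bound
    mode_id[j] <- cur_mode
  }

  # ---- membrane ----------------------------------------------------------
  n_popc <- topo$n_popc; n_chol <- topo$n_chol
  n_lip <- n_popc + n_chol
  hot_res <- if (n_chol > 0 && !is.null(config$hotspot))
    config$hotspot$residues else integer(0)
  n_hot <- length(hot_res)
  n_int <- if (n_chol > n_hot) min(config$n_intercalated, n_chol - n_hot)
           else 0L
  if (n_hot > n_chol) stop("not enough cholesterols for the hotspot set")

  lip_xy <- NULL; lip_leaflet <- NULL; hot_on <- NULL
  if (n_lip > 0) {
    sd_popc <- sqrt(2 * config$D_popc * 1e5 * dt)
    sd_chol <- sqrt(2 * config$D_chol * 1e5 * dt)
    # leaflet split: alternate so both leaflets are (near) evenly filled
    lip_leaflet <- rep_len(c(1, -1), n_lip)
    lip_sd <- c(rep(sd_popc, n_popc), rep(sd_chol, n_chol))
    lip_xy <- array(NA_real_, c(n_lip, 2, n_frames))
    lip_xy[, 1, 1] <- stats::runif(n_lip) * box[1]
    lip_xy[, 2, 1] <- stats::runif(n_lip) * box[2]
    for (j in 2:n_frames) {
      lip_xy[, , j] <- lip_xy[, , j - 1] +
        matrix(stats::rnorm(2 * n_lip, 0, lip_sd), n_lip, 2)
    }
    # hotspot Markov chains (one designated cholesterol per hotspot residue)
    if (n_hot > 0) {
      p_occ <- config$hotspot$occupancy
      q_off <- min(1, dt / config$hotspot$mean_contact)
      q_on <- min(1, q_off * p_occ / (1 - p_occ))
      hot_on <- matrix(FALSE, n_hot, n_frames)
      hot_on[, 1] <- stats::runif(n_hot) < p_occ
      for (j in 2:n_frames) {
        u <- stats::runif(n_hot)
        hot_on[, j] <- ifelse(hot_on[, j - 1], u >= q_off, u < q_on)
      }
    }
  }

  # ---- frame assembly ----------------------------------------------------
  np <- nrow(tmpl$coords)
  n_beads <- nrow(topo$beads)
  coords <- array(NA_real_, c(n_beads, 3, n_frames))
  A0 <- rotate_z(tmpl$coords, zrotA)
  idxA <- seq_len(np); idxB <- np + seq_len(np)
  excl_r <- config$template_radius + 0.9   # cholesterol exclusion radius
  thick <- config$bilayer_thickness

  # designated cholesterol molecule indices (within the cholesterol block):
  # hotspots first (upper leaflet preferred), then intercalating ones
  chol_mol <- which(topo$beads$species[seq_len(n_beads)] == "CHOL")
  chol_first_bead <- chol_mol[seq(1, length.out = n_chol, by = 8)]
  hot_idx <- seq_len(n_hot)                 # cholesterol numbers 1..n_hot
  int_idx <- n_hot + seq_len(n_int)

  hot_geom <- lapply(hot_res, function(rr) {
    k <- match(rr, tmpl$residue_number)
    if (is.na(k)) stop("hotspot residue not in template: ", rr)
    list(az = atan2(tmpl$coords[k, 2], tmpl$coords[k, 1]) * 180 / pi,
         rad = sqrt(sum(tmpl$coords[k, 1:2]^2)) + 0.45,
         z = tmpl$coords[k, 3])
  })

  for (j in seq_len(n_frames)) {
    coords[idxA, , j] <- sweep(A0, 2, -c(posA[j, ], 0))
    Bj <- rotate_z(tmpl$coords, zrotB[j])
    coords[idxB, , j] <- sweep(Bj, 2, -c(posB[j, ], 0))
    if (n_lip > 0) {
      xy <- lip_xy[, , j, drop = FALSE]
      dim(xy) <- c(n_lip, 2)
      if (n_chol > 0) {
        ci <- n_popc + seq_len(n_chol)
        xy[ci, ] <- push_out(xy[ci, , drop = FALSE], posA[j, ], excl_r, box)
        xy[ci, ] <- push_out(xy[ci, , drop = FALSE], posB[j, ], excl_r, box)
        for (h in seq_len(n_hot)) {
          if (hot_on[h, j]) {
            g <- hot_geom[[h]]
            ang <- (g$az + zrotA) * pi / 180
            xy[n_popc + hot_idx[h], ] <- posA[j, ] +
              g$rad * c(cos(ang), sin(ang))
          }
        }
        if (n_int > 0 && bound[j]) {
          dAB <- minimum_image(c(posA[j, ], 0), c(posB[j, ], 0), box)[1, 1:2]
          mid <- posA[j, ] + dAB / 2
          perp <- c(-dAB[2], dAB[1]) / max(sqrt(sum(dAB^2)), 1e-9)
          off <- if (n_int == 1) 0 else seq(-0.3, 0.3, length.out = n_int)
          for (k in seq_len(n_int)) {
            xy[n_popc + int_idx[k], ] <- mid + off[k] * perp
          }
        }
      }
      if (n_popc > 0) {
        pz <- lip_leaflet[seq_len(n_popc)] * thick / 2 +
          stats::rnorm(n_popc, 0, config$z_jitter)
        coords[chol_anchor_popc(topo), , j] <- cbind(xy[seq_len(n_popc), ,
                                                        drop = FALSE], pz)
      }
      if (n_chol > 0) {
        zj <- stats::rnorm(n_chol, 0, config$z_jitter / 2)
        for (c_i in seq_len(n_chol)) {
          lf <- lip_leaflet[n_popc + c_i]
          zoff <- if (n_int > 0 && c_i %in% int_idx && bound[j]) {
            seq(0.7, -0.7, length.out = 8)
          } else if (n_hot > 0 && c_i <= n_hot && hot_on[c_i, j]) {
            # rod centered on the hotspot residue so the contact is
            # guaranteed at the planted lateral offset
            hot_geom[[c_i]]$z + seq(0.7, -0.7, length.out = 8)
          } else chol_z_offsets(thick, lf)
          rows <- chol_first_bead[c_i] + 0:7
          coords[rows, 1, j] <- xy[n_popc + c_i, 1]
          coords[rows, 2, j] <- xy[n_popc + c_i, 2]
          coords[rows, 3, j] <- zoff + zj[c_i]
        }
      }
    }
    # shift z so the bilayer midplane sits at Lz/2, wrap x/y into the box
    coords[, 3, j] <- coords[, 3, j] + box[3] / 2
    coords[, 1, j] <- coords[, 1, j] %% box[1]
    coords[, 2, j] <- coords[, 2, j] %% box[2]
  }

  events <- if (length(events)) do.call(rbind, events)
            else data.frame(time = numeric(0), type = character(0),
                            mode = character(0))
  truth <- list(
    run_id = run_id,
    events = events,
    mode_per_frame = mode_id,
    mode_names = modes$name,
    beta_per_frame = beta_f,
    chi_per_frame = chi_f,
    first_binding_time =
      if (any(events$type == "bind")) min(events$time[events$type == "bind"])
      else Inf,
    D = c(protein = config$D_protein, POPC = config$D_popc,
          CHOL = config$D_chol),
    hotspot = if (n_hot > 0)
      data.frame(residue = hot_res,
                 target_occupancy = config$hotspot$occupancy,
                 realized_occupancy = rowMeans(hot_on))
      else NULL,
    hotspot_on = hot_on,
    zrotA = zrotA, zrotB0 = init$zrotB)

  meta <- list(composition = sprintf("chol%.0f", 100 *
                                       config$cholesterol_fraction),
               cholesterol_fraction = config$cholesterol_fraction)
  list(run = ensemble_run(run_id, times, coords, box, meta), truth = truth)
}

# row indices of the PO4 beads (POPC block precedes cholesterol block)
chol_anchor_popc <- function(topo) {
  which(topo$beads$species == "POPC")
}

# Push xy points radially out of a disc of radius r around `center`
# (minimum image); used for the cholesterol exclusion shell.
push_out <- function(xy, center, r, box) {
  d <- cbind(xy[, 1] - center[1], xy[, 2] - center[2])
  d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
  d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
  dist <- sqrt(rowSums(d^2))
  inside <- dist < r
  if (any(inside)) {
    scale <- r / pmax(dist[inside], 1e-9)
    xy[inside, 1] <- center[1] + d[inside, 1] * scale
    xy[inside, 2] <- center[2] + d[inside, 2] * scale
  }
  xy
}

#' Simulate a full synthetic ensemble
#'
#' @param config a `synthetic_config`.
#' @param run_ids run identifiers (default `1:n_runs`).
#' @return list with `topology`, `runs` (list of `cg_run`), `truth` (list
#'   of ground-truth records) and `config`.
#' @export
simulate_ensemble <- function(config, run_ids = seq_len(config$n_runs)) {
  topo <- synthetic_topology(config)
  sims <- lapply(run_ids, function(id) simulate_run(config, id, topo))
  list(topology = topo,
       runs = lapply(sims, `[[`, "run"),
       truth = lapply(sims, `[[`, "truth"),
       config = config)
}
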