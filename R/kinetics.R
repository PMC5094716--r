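# Binding kinetics and thermodynamics (rate constant, dissociation
# constant, binding free energy), monomer-lifetime statistics, and lateral
# diffusion from mean square displacements.

GAS_CONSTANT <- 8.314      # J mol^-1 K^-1
AVOGADRO <- 6.02214076e23  # mol^-1

#' First-order dimerization rate constant from an ensemble
#'
#' The monomer fraction m(t) (runs not yet dimerized over total runs,
#' treating a run as permanently dimerized after its first binding) is
#' evaluated on the frame grid after an equilibration cut; k is minus the
#' least-squares slope of ln m(t) over the interval where m(t) > 0.
#'
#' @param timelines list of `binding_timeline`s with identical frame
#'   times.
#' @param equilibration_cut initial time discarded before fitting, ns
#'   (default 500).
#' @return k in s^-1 (0, with a warning, if no run dimerizes after the
#'   cut). The fitted monomer-fraction curve is attached as attribute
#'   `monomer_fraction` (data.frame time, m).
#' @export
fit_rate_constant <- function(timelines, equilibration_cut = 500) {
  if (length(timelines) < 1) stop("no timelines")
  times <- timelines[[1]]$times
  fb <- first_binding_times(timelines)
  sel <- times >= equilibration_cut
  tt <- times[sel]
  m <- vapply(tt, function(t) mean(fb > t), numeric(1))
  curve <- data.frame(time = tt, m = m)
  pos <- m > 0
  if (sum(pos) < 2 || all(diff(m[pos]) == 0)) {
    warning("no dimerization after the equilibration cut: k = 0")
    return(structure(0, monomer_fraction = curve))
  }
  fit <- stats::lm(log(m[pos]) ~ tt[pos])
  k <- -unname(stats::coef(fit)[2]) * 1e9   # ns^-1 -> s^-1
  structure(k, monomer_fraction = curve)
}

#' Post-dissociation monomer / dimer time ratio
#'
#' Pooled over runs: only monomer time that follows a dissociation event
#' counts (the equilibrium bookkeeping behind the dissociation constant);
#' censored terminal monomer intervals are included, which biases the
#' resulting binding free energy toward a lower bound.
#'
#' @param timelines list of `binding_timeline`s.
#' @return the dimensionless ratio, with attribute `lower_bound_flag`
#'   (TRUE when no dissociation was observed, in which case the ratio
#'   is 0).
#' @export
estimate_P0_P1 <- function(timelines) {
  p0 <- sum(vapply(timelines, function(tl) tl$post_dissociation_monomer_time,
                   numeric(1)))
  p1 <- sum(vapply(timelines, function(tl) tl$dimer_time, numeric(1)))
  n_diss <- sum(vapply(timelines, function(tl)
    length(tl$dissociation_events), numeric(1)))
  if (p1 == 0) stop("zero dimer time: ratio undefined")
  structure(p0 / p1, lower_bound_flag = n_diss == 0)
}

#' Dissociation constant from the time-ratio and system volume
#'
#' K_D = (P0/P1) * c_std / (N_Av * V) with the standard concentration
#' c_std = 1 mol/l and V the volume of the protein-lipid double layer in
#' nm^3 (converted to liters internally). K_D is dimensionless (relative
#' to 1 mol/l).
#'
#' @param P0_over_P1 post-dissociation monomer / dimer time ratio.
#' @param V double-layer volume in nm^3.
#' @return dimensionless K_D.
#' @export
compute_KD <- function(P0_over_P1, V) {
  if (V <= 0) stop("V must be > 0")
  if (P0_over_P1 < 0) stop("P0/P1 must be >= 0")
  P0_over_P1 / (AVOGADRO * V * 1e-24)
}

#' Binding free energy from the dissociation constant
#'
#' Delta G = R T ln K_D, reported in kJ/mol.
#'
#' @param K_D dimensionless dissociation constant (> 0).
#' @param T temperature in K (default 310).
#' @param R gas constant in J mol^-1 K^-1 (default 8.314).
#' @return Delta G in kJ/mol.
#' @export
compute_dG <- function(K_D, T = 310, R = GAS_CONSTANT) {
  if (any(K_D <= 0)) stop("K_D must be > 0")
  R * T * log(K_D) / 1000
}

#' Kinetics and thermodynamics summary for one ensemble
#'
#' @param timelines list of `binding_timeline`s.
#' @param V double-layer volume, nm^3.
#' @param T temperature, K.
#' @param equilibration_cut see [fit_rate_constant()].
#' @return data.frame with `k` (s^-1), `P0_over_P1`, `V`, `K_D`, `dG`
#'   (kJ/mol), `T`, `lower_bound` flag.
#' @export
kinetics_report <- function(timelines, V, T = 310, equilibration_cut = 500) {
  k <- as.numeric(fit_rate_constant(timelines, equilibration_cut))
  ratio <- estimate_P0_P1(timelines)
  kd <- compute_KD(as.numeric(ratio), V)
  data.frame(k = k, P0_over_P1 = as.numeric(ratio), V = V, K_D = kd,
             dG = if (kd > 0) compute_dG(kd, T) else NA_real_,
             T = T, lower_bound = attr(ratio, "lower_bound_flag"))
}

#' Histogram of post-dissociation monomer lifetimes
#'
#' @param timelines list of `binding_timeline`s.
#' @param bin_width bin width in ns.
#' @return data.frame: `bin_start`, `bin_end`, `count` (uncensored
#'   lifetimes); censored lifetimes are attached as attribute `censored`.
#' @export
lifetime_histogram <- function(timelines, bin_width = 10) {
  lt <- do.call(rbind, lapply(timelines, function(tl) tl$monomer_lifetimes))
  if (is.null(lt) || !nrow(lt)) {
    warning("no monomer lifetimes observed")
    return(structure(data.frame(bin_start = numeric(0),
                                bin_end = numeric(0), count = integer(0)),
                     censored = numeric(0)))
  }
  obs <- lt$lifetime[!lt$censored]
  cen <- lt$lifetime[lt$censored]
  if (length(obs)) {
    breaks <- seq(0, (max(obs) %/% bin_width + 1) * bin_width, bin_width)
    counts <- as.integer(table(cut(obs, breaks, right = FALSE)))
    out <- data.frame(bin_start = breaks[-length(breaks)],
                      bin_end = breaks[-1], count = counts)
  } else {
    out <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0))
  }
  structure(out, censored = cen)
}

# ---------------------------------------------------------------------------
# Lateral diffusion

#' Per-molecule lateral tracks of a species
#'
#' Unwrapped xy center-of-mass tracks of every molecule of a species,
#' suitable for mean-square-displacement analysis.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param species species name (`"protein"`, `"POPC"`, `"CHOL"`).
#' @param molecules optional explicit molecule ids (overrides `species`).
#' @return array `dim = c(n_frames, n_molecules, 2)` of positions in nm.
#' @export
extract_tracks <- function(run, topology, species = "POPC",
                           molecules = NULL) {
  b <- topology$beads
  if (is.null(molecules))
    molecules <- unique(b$molecule_id[b$species == species])
  if (!length(molecules)) stop("no molecules of species ", species)
  nf <- length(run$times)
  nm <- length(molecules)
  tracks <- array(NA_real_, c(nf, nm, 2))
  L <- run$box[1:2]
  # per-frame molecular xy centers: beads reassembled around bead 1 by
  # minimum image (molecules are far smaller than half the box)
  for (m in seq_len(nm)) {
    rows <- which(b$molecule_id == molecules[m])
    if (length(rows) == 1L) {
      tracks[, m, ] <- t(run$coords[rows, 1:2, ])
    } else {
      sub <- run$coords[rows, , , drop = FALSE]
      for (k in 1:2) {
        ref <- sub[1, k, ]
        d <- sweep(sub[, k, , drop = TRUE], 2, ref)
        d <- d - L[k] * round(d / L[k])
        tracks[, m, k] <- ref + colMeans(d)
      }
    }
  }
  # unwrap over time: frame-to-frame jumps beyond half the box are images
  for (k in 1:2) {
    jumps <- tracks[-1, , k, drop = FALSE] - tracks[-nf, , k, drop = FALSE]
    dim(jumps) <- c(nf - 1L, nm)
    jumps <- jumps - L[k] * round(jumps / L[k])
    cs <- apply(jumps, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = nf - 1L)
    tracks[, , k] <- rbind(tracks[1, , k],
                           sweep(cs, 2, tracks[1, , k], "+"))
  }
  tracks
}

#' Time-origin-averaged mean square displacement
#'
#' Ensemble- and time-origin-averaged squared lateral displacement per lag,
#' after optionally subtracting the per-frame center-of-mass track of the
#' whole molecule set (drift removal).
#'
#' @param tracks array `c(n_frames, n_molecules, 2)` of unwrapped xy
#'   positions, nm (see [extract_tracks()]).
#' @param times frame times in ns (uniform stride required).
#' @param remove_com subtract a per-frame center-of-mass track (default
#'   TRUE).
#' @param com_track n_frames x 2 matrix with the center-of-mass track of
#'   the whole membrane-protein system; if NULL, the mean over the
#'   supplied tracks is used (adequate only when they represent the whole
#'   system).
#' @param max_lag_fraction largest lag as a fraction of the track length
#'   (default 0.5).
#' @return data.frame of class `msd_curve`: `lag` (ns), `msd` (nm^2).
#' @export
msd <- function(tracks, times, remove_com = TRUE, com_track = NULL,
                max_lag_fraction = 0.5) {
  nf <- dim(tracks)[1]
  if (nf < 2) stop("need at least two frames")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt))
    stop("frame times must be uniformly strided")
  if (remove_com) {
    com <- if (is.null(com_track)) apply(tracks, c(1, 3), mean)
           else com_track
    tracks <- sweep(tracks, c(1, 3), com)
  }
  lags <- seq_len(max(1L, floor((nf - 1) * max_lag_fraction)))
  val <- vapply(lags, function(l) {
    d <- tracks[(1 + l):nf, , , drop = FALSE] -
      tracks[1:(nf - l), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1))
  structure(data.frame(lag = lags * dt[1], msd = val),
            class = c("msd_curve", "data.frame"))
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Einstein relation in two dimensions: D is a quarter of the
#' least-squares slope of the MSD over the fit window, converted from
#' nm^2/ns to cm^2/s (factor 1e-5).
#'
#' @param msd_curve data.frame with `lag` (ns) and `msd` (nm^2).
#' @param fit_window `c(start, end)` of the fit window in ns (default
#'   5-20 ns).
#' @return D in cm^2/s.
#' @export
diffusion_coefficient <- function(msd_curve, fit_window = c(5, 20)) {
  sel <- msd_curve$lag >= fit_window[1] & msd_curve$lag <= fit_window[2]
  if (sum(sel) < 2)
    stop("fit window lies outside the MSD lag range")
  fit <- stats::lm(msd ~ lag, data = msd_curve[sel, ])
  slope <- unname(stats::coef(fit)[2])       # nm^2 / ns
  (slope / 4) * 1e-5
}

#' Per-run diffusion coefficients aggregated over an ensemble
#'
#' Follows the monomeric-analysis protocol: runs that dimerized before
#' `dimer_cut` ns are excluded, the MSD is computed on the initial
#' `analysis_span` ns, and per-run coefficients are aggregated to mean and
#' standard deviation.
#'
#' @param runs list of `cg_run`s.
#' @param topology matching `cg_topology`.
#' @param timelines matching list of `binding_timeline`s (used for the
#'   dimerization exclusion); NULL disables the exclusion.
#' @param species species name.
#' @param fit_window MSD fit window, ns.
#' @param dimer_cut exclusion horizon, ns (default 250).
#' @param analysis_span initial span used for the MSD, ns (default 200).
#' @return data.frame: `species`, `D` (cm^2/s), `sd`, `n_runs`.
#' @export
diffusion_report <- function(runs, topology, timelines = NULL,
                             species = "POPC", fit_window = c(5, 20),
                             dimer_cut = 250, analysis_span = 200) {
  keep <- seq_along(runs)
  if (!is.null(timelines)) {
    fb <- first_binding_times(timelines)
    keep <- which(fb > dimer_cut)
  }
  if (!length(keep)) stop("no runs qualify for diffusion analysis")
  Ds <- vapply(keep, function(i) {
    run <- runs[[i]]
    sel <- run$times <= run$times[1] + analysis_span
    sub <- ensemble_run(run$run_id, run$times[sel],
                        run$coords[, , sel, drop = FALSE], run$box,
                        run$metadata)
    tr <- extract_tracks(sub, topology, species)
    all_tr <- extract_tracks(sub, topology,
                             molecules = unique(topology$beads$molecule_id))
    com <- apply(all_tr, c(1, 3), mean)
    diffusion_coefficient(msd(tr, sub$times, com_track = com), fit_window)
  }, numeric(1))
  data.frame(species = species, D = mean(Ds),
             sd = if (length(Ds) > 1) stats::sd(Ds) else 0,
             n_runs = length(Ds))
}

# ---------------------------------------------------------------------------
# Derived-percentage utilities

#' Fraction of runs that formed a dimer
#'
#' @param n_dimerized number of runs with a dimer.
#' @param n_total total number of runs.
#' @return fraction in `[0, 1]`.
#' @export
dimerized_fraction <- function(n_dimerized, n_total) n_dimerized / n_total

#' Percent decrease of a value relative to a reference
#'
#' @param value observed value.
#' @param reference baseline value.
#' @return decrease in percent: `100 * (1 - value/reference)`.
#' @export
percent_decrease <- function(value, reference) 100 * (1 - value / reference)
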