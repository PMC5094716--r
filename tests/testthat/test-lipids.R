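# Cholesterol contacts, occupancy, intercalation and bilayer thickness.

# hand-built system: one 3-bead protein rod at the origin plus cholesterol
# rods at chosen lateral distances
contact_topo <- function(n_chol) {
  prot <- data.frame(bead_id = NA, bead_name = "BB", residue_number = 1:3,
                     residue_name = "RES", molecule_id = 1L,
                     species = "protein", type_key = "X", charge = 0)
  chol <- data.frame(bead_id = NA, bead_name = rep(c("ROH",
                                                     paste0("C", 1:7)),
                                                   n_chol),
                     residue_number = rep(seq_len(n_chol), each = 8),
                     residue_name = "CHOL",
                     molecule_id = rep(1L + seq_len(n_chol), each = 8),
                     species = "CHOL", type_key = "X", charge = 0)
  b <- rbind(prot, chol)
  b$bead_id <- seq_len(nrow(b))
  topology(b, nonbonded = data.frame(type_i = "X", type_j = "X",
                                     C6 = 1, C12 = 1e-3))
}

chol_rod <- function(x, y, ztop = 1.0) cbind(x, y, ztop - 0.2 * (0:7))

test_that("cholesterol contact detection follows the first-shell cutoff", {
  topo <- contact_topo(2)
  prot <- cbind(0, 0, c(-0.3, 0, 0.3))
  co <- rbind(prot, chol_rod(0.5, 0, 0.3), chol_rod(0.7, 0.7, 0.3))
  fr <- trajectory_frame(0, co, c(10, 10, 10))
  bound <- cholesterol_bound(fr, 1:3, topo)
  expect_equal(bound, 2L)               # 0.5 nm: bound; ~0.99 nm: not
  expect_length(cholesterol_bound(fr, 1:3, topo, cutoff = 0.4), 0)
  expect_error(cholesterol_bound(fr, 1:3, topo, cutoff = -1), "cutoff")
})

test_that("contact detection agrees with the exhaustive pairwise oracle", {
  set.seed(13)
  topo <- contact_topo(6)
  box <- c(6, 6, 6)
  for (rep in 1:20) {
    prot <- matrix(runif(9, 0, 6), 3, 3)
    chols <- do.call(rbind, lapply(1:6, function(i)
      chol_rod(runif(1, 0, 6), runif(1, 0, 6), runif(1, 0, 6))))
    fr <- trajectory_frame(0, rbind(prot, chols), box)
    got <- cholesterol_bound(fr, 1:3, topo)
    # oracle: explicit loop over every cholesterol bead x protein bead
    want <- integer(0)
    for (c_i in 1:6) {
      rows <- 3 + (c_i - 1) * 8 + 1:8
      hit <- FALSE
      for (r in rows) for (p in 1:3) {
        if (minimum_image_distance(fr$coordinates[r, ],
                                   fr$coordinates[p, ], box) < 0.62)
          hit <- TRUE
      }
      if (hit) want <- c(want, c_i + 1L)   # molecule ids start at 2
    }
    expect_identical(got, sort(want))
  }
})

test_that("occupancy is monotone in the cutoff and zero without cholesterol", {
  cfg <- quick_config(run_length = 120, include_lipids = TRUE,
                      cholesterol_fraction = 0.15, association_rate = 0,
                      hotspot = list(residues = 36L, occupancy = 0.5,
                                     mean_contact = 5), seed = 3)
  topo <- synthetic_topology(cfg)
  run <- simulate_run(cfg, 1, topo)$run
  occ1 <- residue_occupancy(run, topo, 1L, c(20, 120), cutoff = 0.62)
  occ2 <- residue_occupancy(run, topo, 1L, c(20, 120), cutoff = 0.9)
  expect_true(all(occ2$occupancy >= occ1$occupancy - 1e-12))
  expect_error(residue_occupancy(run, topo, 1L, c(500, 900)), "window")

  cfg0 <- quick_config(run_length = 60, include_lipids = TRUE,
                       cholesterol_fraction = 0, association_rate = 0,
                       seed = 3)
  topo0 <- synthetic_topology(cfg0)
  run0 <- simulate_run(cfg0, 1, topo0)$run
  occ0 <- residue_occupancy(run0, topo0, 1L, c(0, 60))
  expect_true(all(occ0$occupancy == 0))
  expect_true(all(occ0$mean_contact_ns == 0))
})

test_that("a single contiguous contact yields its own duration as mean contact time", {
  topo <- contact_topo(1)
  nf <- 21
  co <- array(NA_real_, c(11, 3, nf))
  prot <- cbind(0, 0, c(-0.3, 0, 0.3))
  for (i in 1:nf) {
    near <- i >= 6 && i <= 11            # 6 frames in contact (6 ns)
    co[1:3, , i] <- prot
    co[4:11, , i] <- chol_rod(if (near) 0.5 else 3, 0, 0.3)
  }
  run <- ensemble_run(1, 0:(nf - 1), co + 5, c(10, 10, 10))
  occ <- residue_occupancy(run, topo, 1L, c(0, 20))
  expect_equal(unique(occ$mean_contact_ns), 6)
  expect_equal(unique(occ$occupancy), 6 / 21)
})

test_that("intercalation counts cholesterols bound to both receptors simultaneously", {
  # two 3-bead receptor rods with one cholesterol between them
  prot <- data.frame(bead_id = NA, bead_name = "BB", residue_number = 1:3,
                     residue_name = "RES", molecule_id = 1L,
                     species = "protein", type_key = "X", charge = 0)
  prot2 <- transform(prot, molecule_id = 2L)
  chol <- data.frame(bead_id = NA,
                     bead_name = c("ROH", paste0("C", 1:7)),
                     residue_number = 1, residue_name = "CHOL",
                     molecule_id = 3L, species = "CHOL", type_key = "X",
                     charge = 0)
  b <- rbind(prot, prot2, chol); b$bead_id <- seq_len(nrow(b))
  topo <- topology(b, nonbonded = data.frame(type_i = "X", type_j = "X",
                                             C6 = 1, C12 = 1e-3))
  mk <- function(cx) trajectory_frame(0, rbind(
    cbind(2, 2, c(1.7, 2, 2.3)), cbind(3, 2, c(1.7, 2, 2.3)),
    chol_rod(cx, 2, 2.7)), c(8, 8, 8))
  expect_equal(intercalation_count(mk(2.5), 1:3, 4:6, topo), 1)
  expect_equal(intercalation_count(mk(6.5), 1:3, 4:6, topo), 0)
  expect_error(intercalation_count(mk(2.5), 1:4, 4:6, topo), "disjoint")
})

test_that("planted interfacial cholesterols are detected in nearly all bound frames", {
  cfg <- quick_config(run_length = 150, include_lipids = TRUE,
                      cholesterol_fraction = 0.15,
                      association_rate = 0.2, dissociation_rate = 0,
                      n_intercalated = 2L,
                      dimer_modes = data.frame(name = "TM3,4/TM3,4",
                                               beta = 257.1, chi = 257.1,
                                               weight = 1, spread = 5),
                      seed = 18)
  topo <- synthetic_topology(cfg)
  sim <- simulate_run(cfg, 1, topo)
  bnd <- which(sim$truth$mode_per_frame > 0)
  expect_gt(length(bnd), 30)
  bA <- select_beads(topo, molecule = 1L)
  bB <- select_beads(topo, molecule = 2L)
  counts <- vapply(bnd, function(i)
    intercalation_count(get_frame(sim$run, i), bA, bB, topo), integer(1))
  expect_gte(mean(counts >= 2), 0.9)
  rep <- intercalation_report(sim$run, topo, window = 50)
  expect_gte(rep$p_at_least_one, 0.9)
})

test_that("global bilayer thickness equals the planted leaflet separation", {
  for (th in c(4.2, 4.25)) {
    cfg <- quick_config(run_length = 30, include_lipids = TRUE,
                        association_rate = 0, bilayer_thickness = th,
                        seed = 5)
    topo <- synthetic_topology(cfg)
    run <- simulate_run(cfg, 1, topo)$run
    expect_equal(bilayer_thickness(run, topo), th, tolerance = 0.03 / th)
  }
  # all reference beads in one plane: leaflets indistinguishable
  cfg1 <- quick_config(run_length = 10, include_lipids = TRUE,
                       association_rate = 0, seed = 5)
  topo1 <- synthetic_topology(cfg1)
  run1 <- simulate_run(cfg1, 1, topo1)$run
  po4 <- which(topo1$beads$bead_name == "PO4")
  run1$coords[po4, 3, ] <- 4.5
  expect_error(bilayer_thickness(run1, topo1), "unimodal")
})

test_that("local thickness tracks the membrane around the protein", {
  cfg <- quick_config(run_length = 40, include_lipids = TRUE,
                      association_rate = 0, seed = 6)
  topo <- synthetic_topology(cfg)
  run <- simulate_run(cfg, 1, topo)$run
  glob <- bilayer_thickness(run, topo)
  loc <- local_thickness(run, topo, radius = 1.2)
  expect_false(is.na(loc))
  expect_equal(loc, glob, tolerance = 0.05)

  # planted thinning: pull qualifying reference beads inward by 0.15 nm
  # per leaflet and observe the reduced local thickness
  run2 <- run
  po4 <- which(topo$beads$bead_name == "PO4")
  prot <- which(topo$beads$species == "protein")
  for (i in seq_along(run2$times)) {
    fr <- get_frame(run2, i)
    d <- apply(
      vapply(prot, function(p) minimum_image_distance(
        fr$coordinates[po4, , drop = FALSE],
        matrix(fr$coordinates[p, ], nrow = length(po4), ncol = 3,
               byrow = TRUE), fr$box), numeric(length(po4))), 1, min)
    near <- po4[d < 1.2]
    z <- run2$coords[near, 3, i]
    run2$coords[near, 3, i] <- z - sign(z - 4.5) * 0.15
  }
  loc2 <- local_thickness(run2, topo, radius = 1.2)
  expect_equal(loc - loc2, 0.3, tolerance = 0.1)

  # protein-free qualifying set: flagged missing value
  far <- run
  far$coords[po4, 1, ] <- (far$coords[po4, 1, ] * 0) + 7
  far$coords[po4, 2, ] <- 7
  expect_warning(v <- local_thickness(far, topo, radius = 0.01),
                 "no frame")
  expect_true(is.na(v))
})
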