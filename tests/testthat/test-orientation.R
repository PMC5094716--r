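# Internal frames, relative-orientation angles and helix tilts.

bigbox <- c(1e6, 1e6, 1e6)

template_pair <- function(beta, chi, tmpl = build_protein_template(
                            reduced_helix_ranges())) {
  phi <- wrap360(180 + beta - chi)
  d <- contact_distance(tmpl, beta, chi) + 1     # comfortably separated
  ang <- beta * pi / 180
  A <- sweep(rotate_z(tmpl$coords, 0), 2, 0)
  B <- sweep(rotate_z(tmpl$coords, phi), 2,
             -c(d * cos(ang), d * sin(ang), 0))
  ref <- which(tmpl$helix %in% c("TM5", "TM6"))
  list(fA = internal_frame(A, ref), fB = internal_frame(B, ref),
       tmpl = tmpl)
}

test_that("internal frame is equivariant under rotation and translation", {
  tmpl <- build_protein_template(reduced_helix_ranges())
  ref <- which(tmpl$helix %in% c("TM5", "TM6"))
  f0 <- internal_frame(tmpl$coords, ref)
  expect_equal(f0$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f0$x, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(f0$z, c(0, 0, 1))
  # orthonormal right-handed triad
  expect_equal(sum(f0$x * f0$y), 0, tolerance = 1e-12)
  expect_equal(crossprod(f0$y), matrix(1), tolerance = 1e-12,
               ignore_attr = TRUE)

  f90 <- internal_frame(rotate_z(tmpl$coords, 90), ref)
  expect_equal(f90$x, c(0, 1, 0), tolerance = 1e-12)

  ft <- internal_frame(sweep(tmpl$coords, 2, -c(5, 5, 0)), ref)
  expect_equal(ft$origin, c(5, 5, 0), tolerance = 1e-12)
  expect_equal(ft$x, f0$x)

  expect_error(internal_frame(matrix(0, 5, 3), 1:2), "degenerate")
})

test_that("worked relative-orientation cases reproduce the reference angles", {
  # both monomers identically oriented (phi = 0), B at A's beta = 0
  # direction: the face-to-back dimer, chi = 180
  p <- template_pair(0, 180)
  rec <- relative_orientation(p$fA, p$fB, bigbox)
  expect_equal(circular_distance(rec$beta, 0), 0, tolerance = 1e-9)
  expect_equal(circular_distance(rec$phi, 0), 0, tolerance = 1e-9)
  expect_equal(rec$chi, 180, tolerance = 1e-9)

  # phi = 0, beta = 180: the mirrored face-to-back case, chi = 0
  p <- template_pair(180, 0)
  rec <- relative_orientation(p$fA, p$fB, bigbox)
  expect_equal(rec$beta, 180, tolerance = 1e-9)
  expect_equal(wrap360(rec$chi + 180) - 180, 0, tolerance = 1e-9)

  # symmetric face-to-face reference configuration: beta = chi = 0
  p <- template_pair(0, 0)
  rec <- relative_orientation(p$fA, p$fB, bigbox)
  expect_equal(circular_distance(rec$beta, 0), 0, tolerance = 1e-9)
  expect_equal(wrap360(rec$chi + 180) - 180, 0, tolerance = 1e-9)
  expect_equal(rec$phi, 180, tolerance = 1e-9)

  # direct formula evaluation: beta = 90, phi = 270 => chi = 0
  p <- template_pair(90, wrap360(180 + 90 - 270))
  rec <- relative_orientation(p$fA, p$fB, bigbox)
  expect_equal(rec$phi, 270, tolerance = 1e-9)
  expect_equal(wrap360(rec$chi + 180) - 180, 0, tolerance = 1e-9)
})

test_that("the chi identity holds exactly on random poses and swapping maps (beta,chi) to (chi,beta)", {
  set.seed(17)
  for (r in 1:40) {
    beta <- runif(1) * 360; chi <- runif(1) * 360
    p <- template_pair(beta, chi)
    rec <- relative_orientation(p$fA, p$fB, bigbox)
    expect_equal(rec$chi, wrap360(180 + rec$beta - rec$phi),
                 tolerance = 1e-9)
    expect_equal(circular_distance(rec$beta, beta), 0, tolerance = 1e-6)
    expect_equal(circular_distance(rec$chi, chi), 0, tolerance = 1e-6)
    swapped <- relative_orientation(p$fB, p$fA, bigbox)
    expect_equal(circular_distance(swapped$beta, rec$chi), 0,
                 tolerance = 1e-6)
    expect_equal(circular_distance(swapped$chi, rec$beta), 0,
                 tolerance = 1e-6)
  }
})

test_that("a rigid rotation of the whole system leaves beta, phi, chi unchanged", {
  set.seed(19)
  tmpl <- build_protein_template(reduced_helix_ranges())
  ref <- which(tmpl$helix %in% c("TM5", "TM6"))
  for (r in 1:10) {
    beta <- runif(1) * 360; chi <- runif(1) * 360
    p <- template_pair(beta, chi, tmpl)
    rec <- relative_orientation(p$fA, p$fB, bigbox)
    g <- runif(1) * 360
    rot <- function(f) {
      co <- rbind(f$origin, f$origin + f$x, f$origin + f$y)
      co <- rotate_z(co, g)
      internal_frame_like <- list(origin = co[1, ], x = co[2, ] - co[1, ],
                                  y = co[3, ] - co[1, ], z = f$z)
      class(internal_frame_like) <- "internal_frame"
      internal_frame_like
    }
    rec2 <- relative_orientation(rot(p$fA), rot(p$fB), bigbox)
    expect_equal(circular_distance(rec2$beta, rec$beta), 0,
                 tolerance = 1e-6)
    expect_equal(circular_distance(rec2$phi, rec$phi), 0, tolerance = 1e-6)
    expect_equal(circular_distance(rec2$chi, rec$chi), 0, tolerance = 1e-6)
  }
})

test_that("helix tilt reproduces analytic rod orientations", {
  rod <- cbind(0, 0, seq(0, 3, length.out = 10))
  expect_equal(helix_tilt(rod), 0, tolerance = 1e-5)
  rod45 <- cbind(seq(0, 3, length.out = 10) / sqrt(2), 0,
                 seq(0, 3, length.out = 10) / sqrt(2))
  expect_equal(helix_tilt(rod45), 45, tolerance = 1e-5)
  # analytic oracle: rotating a z-rod by polar angle theta tilts it by
  # exactly theta (folded into [0, 90])
  set.seed(3)
  for (r in 1:20) {
    theta <- runif(1, 0, 180)
    th <- theta * pi / 180
    Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                 3, 3, byrow = TRUE)
    tilted <- rod %*% t(Ry)
    expect_equal(helix_tilt(tilted), min(theta, 180 - theta),
                 tolerance = 1e-6)
  }
  # invariance to translation and bead-order reflection
  expect_equal(helix_tilt(sweep(rod45, 2, -c(3, -2, 1))), 45,
               tolerance = 1e-9)
  expect_equal(helix_tilt(rod45[10:1, ]), 45, tolerance = 1e-9)
  expect_error(helix_tilt(rod45[c(1, 1, 1), ]), "degenerate")
})

test_that("the final-window orientation sample excludes unbound runs and flags short ones", {
  cfg <- quick_config(run_length = 120, association_rate = 0.2,
                      dissociation_rate = 0, seed = 8)
  topo <- synthetic_topology(cfg)
  sim <- simulate_run(cfg, 1, topo)
  tl <- classify_states(energy_series(sim$run, topo))
  rec <- dimer_angle_sample(sim$run, topo, tl, window = 50)
  expect_false(is.null(rec))
  expect_true(all(rec$time > 120 - 50))
  expect_false(attr(rec, "truncated"))
  # planted circular means recovered within the angular jitter
  bnd <- match(round(rec$time), sim$run$times)
  expect_lt(circular_distance(circular_mean(rec$beta),
                              circular_mean(sim$truth$beta_per_frame[bnd])),
            1e-6)

  # a run with no binding ends unbound and is excluded
  cfg0 <- quick_config(association_rate = 0, seed = 9)
  topo0 <- synthetic_topology(cfg0)
  sim0 <- simulate_run(cfg0, 1, topo0)
  tl0 <- classify_states(energy_series(sim0$run, topo0))
  expect_null(dimer_angle_sample(sim0$run, topo0, tl0))

  # run shorter than the window: truncated flag set
  cfg2 <- quick_config(run_length = 30, association_rate = 0.5, seed = 10)
  topo2 <- synthetic_topology(cfg2)
  sim2 <- simulate_run(cfg2, 1, topo2)
  tl2 <- classify_states(energy_series(sim2$run, topo2))
  rec2 <- dimer_angle_sample(sim2$run, topo2, tl2, window = 50)
  if (!is.null(rec2)) expect_true(attr(rec2, "truncated"))
})
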