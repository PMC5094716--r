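# Periodic KDE, maxima, watershed and label bookkeeping on the torus.

test_that("periodic KDE matches the brute-force image-sum oracle", {
  set.seed(2)
  n <- 60
  pts <- data.frame(beta = c(rnorm(n / 2, 90, 15) %% 360,
                             rnorm(n / 2, 300, 20) %% 360),
                    chi = c(rnorm(n / 2, 45, 15) %% 360,
                            rnorm(n / 2, 200, 20) %% 360))
  bw <- 12; G <- 72L
  f <- periodic_kde(pts, bw, G)
  cell <- 360 / G
  centers <- (seq_len(G) - 0.5) * cell
  brute <- matrix(0, G, G)
  for (m in -1:1) for (mm in -1:1) {
    kb <- outer(centers, pts$beta, function(c, x) dnorm(c - x + 360 * m, 0, bw))
    kc <- outer(centers, pts$chi, function(c, x) dnorm(c - x + 360 * mm, 0, bw))
    brute <- brute + kb %*% t(kc)
  }
  brute <- brute / nrow(pts)
  brute <- brute / (sum(brute) * cell^2)
  expect_lt(max(abs(f$grid - brute)), 1e-9)
  # normalized field
  expect_equal(sum(f$grid) * cell^2, 1, tolerance = 1e-6)
  expect_true(all(f$grid >= 0))
  expect_error(periodic_kde(pts[0, ], bw, G), "empty")
})

test_that("KDE respects wraparound symmetry near the domain edge", {
  f <- periodic_kde(data.frame(beta = 359, chi = 359), 5, 360L)
  # cell centers 1.5 and 356.5 are both 2.5 degrees from the point
  # circularly, so their densities agree by wraparound symmetry
  expect_equal(f$grid[2, 2], f$grid[357, 357], tolerance = 1e-12)
  # a point at a cell center puts the global maximum in that cell
  f2 <- periodic_kde(data.frame(beta = 359.5, chi = 359.5), 5, 360L)
  expect_equal(as.vector(arrayInd(which.max(f2$grid), dim(f2$grid))),
               c(360L, 360L))
})

test_that("maxima detection finds planted bumps and handles the constant field", {
  f1 <- periodic_kde(data.frame(beta = 120, chi = 240), 15, 72L)
  m1 <- find_maxima(f1)
  expect_equal(nrow(m1), 1)
  expect_lt(circular_distance(m1$beta, 120), 360 / 72 + 1e-9)
  expect_lt(circular_distance(m1$chi, 240), 360 / 72 + 1e-9)

  set.seed(8)
  pts <- data.frame(beta = c(rnorm(500, 90, 8), rnorm(500, 270, 8)) %% 360,
                    chi = c(rnorm(500, 90, 8), rnorm(500, 270, 8)) %% 360)
  f2 <- periodic_kde(pts, 10, 72L)
  m2 <- find_maxima(f2)
  expect_equal(nrow(m2), 2)
  ord <- order(m2$beta)
  expect_lt(circular_distance(m2$beta[ord[1]], 90), 6)
  expect_lt(circular_distance(m2$chi[ord[2]], 270), 6)

  # constant field: no strict local maximum; degenerate case documented
  fc <- f1; fc$grid[] <- 1 / (360^2)
  expect_equal(nrow(find_maxima(fc)), 0)
  expect_error(watershed(fc, find_maxima(fc)), "at least one maximum")
})

test_that("single-maximum watershed labels the whole torus without boundaries", {
  f <- periodic_kde(data.frame(beta = 45, chi = 315), 20, 48L)
  lab <- watershed(f)
  expect_true(all(lab$labels == 1L))
  sp <- label_spreading(f, lab)
  expect_equal(sp$spreading, 1, tolerance = 1e-6)
  expect_equal(attr(sp, "watershed_mass"), 0)
})

test_that("two equal bumps split the torus symmetrically", {
  set.seed(21)
  n <- 4000
  pts <- data.frame(beta = c(rnorm(n, 90, 12), rnorm(n, 270, 12)) %% 360,
                    chi = rep(180, 2 * n))
  f <- periodic_kde(pts, 10, 72L)
  lab <- watershed(f)
  expect_equal(nrow(lab$maxima), 2)
  sp <- label_spreading(f, lab)
  expect_equal(sum(sp$spreading) + attr(sp, "watershed_mass"), 1,
               tolerance = 1e-6)
  expect_equal(sp$spreading[1], sp$spreading[2], tolerance = 1e-3)
  # boundary meridians near beta = 0 and beta = 180, equidistant from the
  # bumps by symmetry
  ws <- which(lab$labels == 0L, arr.ind = TRUE)
  if (nrow(ws)) {
    bws <- f$centers[ws[, 1]]
    expect_true(all(pmin(circular_distance(bws, 0),
                         circular_distance(bws, 180)) < 15))
  }
})

test_that("planted mixture weights are recovered by label spreading", {
  set.seed(33)
  n <- 10000
  w <- c(0.7, 0.3)
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  centers <- rbind(c(90, 90), c(270, 270))
  pts <- data.frame(beta = (centers[comp, 1] + rnorm(n, 0, 10)) %% 360,
                    chi = (centers[comp, 2] + rnorm(n, 0, 10)) %% 360)
  f <- periodic_kde(pts, 10, 72L)
  lab <- watershed(f)
  sp <- label_spreading(f, lab)
  got <- sp$spreading[order(sp$beta)]
  expect_equal(got[1], mean(comp == 1), tolerance = 0.02)
  expect_equal(got[2], mean(comp == 2), tolerance = 0.02)
})

test_that("frame assignment uses containing cells with the deterministic boundary rule", {
  set.seed(44)
  pts <- data.frame(beta = c(rnorm(2000, 90, 10), rnorm(2000, 270, 10)) %% 360,
                    chi = c(rnorm(2000, 120, 10), rnorm(2000, 300, 10)) %% 360)
  f <- periodic_kde(pts, 10, 72L)
  lab <- watershed(f)
  # a frame exactly at each maximum maps to that label
  for (l in seq_len(nrow(lab$maxima))) {
    a <- assign_frames(data.frame(beta = lab$maxima$beta[l],
                                  chi = lab$maxima$chi[l]), lab)
    expect_equal(a, l)
  }
  # watershed cells resolve deterministically to a real label
  ws <- which(lab$labels == 0L, arr.ind = TRUE)
  if (nrow(ws)) {
    b <- f$centers[ws[, 1]]; c2 <- f$centers[ws[, 2]]
    a1 <- assign_frames(data.frame(beta = b, chi = c2), lab)
    a2 <- assign_frames(data.frame(beta = b, chi = c2), lab)
    expect_identical(a1, a2)
    expect_true(all(a1 %in% seq_len(nrow(lab$maxima))))
  }
})

test_that("the whole segmentation stack is equivariant under a common circular shift", {
  set.seed(55)
  pts <- data.frame(beta = c(rnorm(1500, 60, 9), rnorm(1500, 200, 9)) %% 360,
                    chi = c(rnorm(1500, 330, 9), rnorm(1500, 100, 9)) %% 360)
  shift <- 40
  G <- 72L
  stopifnot(shift %% (360 / G) == 0)      # whole number of cells
  f0 <- periodic_kde(pts, 10, G)
  f1 <- periodic_kde(data.frame(beta = (pts$beta + shift) %% 360,
                                chi = (pts$chi + shift) %% 360), 10, G)
  k <- shift / (360 / G)
  rot <- function(M, k) M[c((G - k + 1):G, 1:(G - k)),
                          c((G - k + 1):G, 1:(G - k))]
  expect_equal(f1$grid, rot(f0$grid, k), tolerance = 1e-12)
  m0 <- find_maxima(f0); m1 <- find_maxima(f1)
  expect_equal(nrow(m0), nrow(m1))
  expect_setequal(round(wrap360(m0$beta + shift), 6), round(m1$beta, 6))
  l0 <- watershed(f0, m0); l1 <- watershed(f1, m1)
  s0 <- label_spreading(f0, l0); s1 <- label_spreading(f1, l1)
  expect_equal(sort(s0$spreading), sort(s1$spreading), tolerance = 1e-9)
})

test_that("population report normalizes per group and drops empty groups", {
  a <- c(1, 1, 1, 2)
  p <- population_report(a)
  expect_equal(p$population, c(0.75, 0.25))
  p2 <- population_report(rep(1, 5))
  expect_equal(p2$population, 1)
  g <- c("x", "x", "y", "y")
  p3 <- population_report(c(1, 2, 1, 1), g)
  expect_equal(p3$population[p3$group == "y" & p3$label == 1], 1)
  expect_error(population_report(integer(0)), "no assigned frames")
})
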