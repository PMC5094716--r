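# Dimer-configuration density on the periodic (beta, chi) plane: wrapped
# kernel density estimation, local maxima, watershed segmentation by
# simulated immersion with toroidal topology, label spreading, and
# frame-to-label assignment.

#' Periodic kernel density estimate on the (beta, chi) torus
#'
#' Wrapped-Gaussian product kernel evaluated at the cell centers of a
#' G x G grid over `[0, 360)^2` (beta on x, chi on y). Periodic images are
#' summed until an additional image layer changes no cell by more than
#' 1e-12. The field is normalized so that sum(values) * cell_area = 1.
#'
#' @param points data.frame or matrix with columns `beta`, `chi`
#'   (degrees).
#' @param bandwidth kernel standard deviation in degrees (default 10).
#' @param grid_size number of cells per axis (default 360, i.e. 1-degree
#'   cells).
#' @return object of class `height_field`: list with `grid` (G x G matrix,
#'   rows = beta cells, columns = chi cells), `cell` (cell size, degrees)
#'   and `centers` (cell-center angles).
#' @export
periodic_kde <- function(points, bandwidth = 10, grid_size = 360L) {
  points <- as.data.frame(points)
  if (!nrow(points)) stop("empty point set")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  cell <- 360 / grid_size
  centers <- (seq_len(grid_size) - 0.5) * cell
  kb <- wrapped_kernel_matrix(points$beta, centers, bandwidth)
  kc <- wrapped_kernel_matrix(points$chi, centers, bandwidth)
  # density(cell_b, cell_c) = mean_i K(b - beta_i) K(c - chi_i)
  grid <- (kb %*% t(kc)) / nrow(points)
  grid <- grid / (sum(grid) * cell^2)
  structure(list(grid = grid, cell = cell, centers = centers),
            class = "height_field")
}

# G x n matrix of wrapped-normal kernel values K(center_g - x_i); image
# terms added until the largest added contribution falls below 1e-12.
wrapped_kernel_matrix <- function(x, centers, bw) {
  d0 <- outer(centers, wrap360(x), "-")
  total <- stats::dnorm(d0, 0, bw)
  m <- 1
  repeat {
    add <- stats::dnorm(d0 + 360 * m, 0, bw) + stats::dnorm(d0 - 360 * m,
                                                            0, bw)
    total <- total + add
    if (max(add) <= 1e-12) break
    m <- m + 1
  }
  total
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("height_field: %d x %d grid, %.3g-degree cells\n",
              nrow(x$grid), ncol(x$grid), x$cell))
  invisible(x)
}

# toroidal neighbor index shifts; i is 1-based linear index of a G x G
# grid stored column-major (row = beta, col = chi)
torus_shift <- function(idx, di, dj, G) {
  i0 <- (idx - 1L) %% G          # 0-based row
  j0 <- (idx - 1L) %/% G         # 0-based col
  ((j0 + dj) %% G) * G + ((i0 + di) %% G) + 1L
}

# offsets of the Chebyshev ring/disc neighborhoods used by the watershed:
# level 1 = 4-neighborhood, level 2 = 8-neighborhood, level r>2 =
# Chebyshev disc of radius r-1.
neighborhood_offsets <- function(level) {
  if (level == 1L) return(cbind(di = c(-1L, 1L, 0L, 0L),
                                dj = c(0L, 0L, -1L, 1L)))
  r <- level - 1L
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[!(g$di == 0 & g$dj == 0), ]
  as.matrix(g)
}

#' Local maxima of a height field
#'
#' Cells strictly higher than all eight toroidal neighbors, with height at
#' least `min_height_fraction` of the global maximum. Plateau components
#' (equal-height cells jointly above their surroundings) are reduced to
#' the cell with the lowest linear index.
#'
#' @param field a `height_field`.
#' @param min_height_fraction noise floor as a fraction of the global
#'   maximum (default 0.05).
#' @return data.frame: `index` (linear cell index), `beta`, `chi` (cell
#'   centers, degrees), `height`.
#' @export
find_maxima <- function(field, min_height_fraction = 0.05) {
  h <- field$grid
  G <- nrow(h)
  idx <- seq_len(G * G)
  off8 <- neighborhood_offsets(2L)
  nb_max <- rep(-Inf, G * G)
  nb_all_le <- rep(TRUE, G * G)
  for (k in seq_len(nrow(off8))) {
    nb <- torus_shift(idx, off8[k, 1], off8[k, 2], G)
    nb_max <- pmax(nb_max, h[nb])
  }
  cand <- which(h >= nb_max & h >= min_height_fraction * max(h))
  strict <- cand[h[cand] > nb_max[cand]]
  flat <- setdiff(cand, strict)
  reps <- integer(0)
  if (length(flat)) {
    # group equal-height flat candidates by 8-connectivity; a plateau
    # component is a maximum only if every adjacent outside cell is
    # strictly lower; it is represented by its lowest linear index
    remaining <- flat
    while (length(remaining)) {
      comp <- remaining[1]
      frontier <- comp
      while (length(frontier)) {
        nbs <- unique(as.vector(vapply(seq_len(nrow(off8)), function(k)
          torus_shift(frontier, off8[k, 1], off8[k, 2], G),
          integer(length(frontier)))))
        frontier <- setdiff(intersect(nbs, remaining), comp)
        comp <- c(comp, frontier)
      }
      all_nbs <- unique(as.vector(vapply(seq_len(nrow(off8)), function(k)
        torus_shift(comp, off8[k, 1], off8[k, 2], G),
        integer(length(comp)))))
      outside <- setdiff(all_nbs, comp)
      if (length(outside) && all(h[outside] < h[comp[1]]))
        reps <- c(reps, min(comp))
      remaining <- setdiff(remaining, comp)
    }
  }
  sel <- sort(c(strict, reps))
  if (!length(sel))
    return(data.frame(index = integer(0), beta = numeric(0),
                      chi = numeric(0), height = numeric(0)))
  i0 <- (sel - 1L) %% G; j0 <- (sel - 1L) %/% G
  data.frame(index = sel,
             beta = field$centers[i0 + 1L],
             chi = field$centers[j0 + 1L],
             height = h[sel])
}

#' Watershed segmentation by simulated immersion on the torus
#'
#' Cells are sorted by descending height (ties broken by linear index) and
#' visited in order: a cell acquires the label that is unique among its
#' already-labeled 4-neighbors, or the watershed marker if two or more
#' distinct labels are present. Cells left unassigned by a full pass are
#' re-processed with a grown neighborhood (4 -> 8 -> Chebyshev radius r+1)
#' whenever a pass assigns no new cell, until every cell is assigned.
#'
#' @param field a `height_field`.
#' @param maxima data.frame from [find_maxima()] (its `index` column seeds
#'   the labels, numbered in row order).
#' @return object of class `label_image`: list with `labels` (G x G
#'   integer matrix; 0 marks watershed cells), `maxima`, `cell`,
#'   `centers`, and `filled` (watershed cells resolved to the nearest
#'   label for frame assignment).
#' @export
watershed <- function(field, maxima = find_maxima(field)) {
  if (!nrow(maxima)) stop("watershed requires at least one maximum")
  h <- field$grid
  G <- nrow(h)
  n <- G * G
  lab <- integer(n)            # 0 = unassigned
  ws <- logical(n)             # watershed marker
  lab[maxima$index] <- seq_len(nrow(maxima))
  ord <- order(-as.vector(h), seq_len(n))
  pending <- ord[lab[ord] == 0L]
  level <- 1L
  while (length(pending)) {
    offs <- neighborhood_offsets(level)
    assigned_any <- FALSE
    still <- logical(length(pending))
    for (q in seq_along(pending)) {
      i <- pending[q]
      nbs <- torus_shift(i, offs[, 1], offs[, 2], G)
      labs <- unique(lab[nbs])
      labs <- labs[labs > 0L]
      if (length(labs) == 1L) {
        lab[i] <- labs
        assigned_any <- TRUE
      } else if (length(labs) >= 2L) {
        ws[i] <- TRUE
        assigned_any <- TRUE
      } else {
        still[q] <- TRUE
      }
    }
    pending <- pending[still]
    if (length(pending) && !assigned_any) level <- level + 1L
  }
  labels <- matrix(lab, G, G)
  labels[matrix(ws, G, G)] <- 0L
  structure(list(labels = labels, maxima = maxima, cell = field$cell,
                 centers = field$centers,
                 filled = fill_watershed(labels, G)),
            class = "label_image")
}

# Resolve watershed (0) cells to the nearest labeled cell by toroidal
# Chebyshev distance (iterative 8-neighborhood dilation); ties take the
# lower label id.
fill_watershed <- function(labels, G) {
  filled <- as.vector(labels)
  off8 <- neighborhood_offsets(2L)
  idx <- seq_len(G * G)
  while (any(filled == 0L)) {
    zero <- which(filled == 0L)
    best <- rep(.Machine$integer.max, length(zero))
    for (k in seq_len(nrow(off8))) {
      nb <- torus_shift(zero, off8[k, 1], off8[k, 2], G)
      v <- filled[nb]
      ok <- v > 0L & v < best
      best[ok] <- v[ok]
    }
    newly <- best < .Machine$integer.max
    if (!any(newly)) stop("no labeled cells to spread from")
    filled[zero[newly]] <- best[newly]
  }
  matrix(filled, G, G)
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: %d labels on a %d x %d torus (%d watershed cells)\n",
              nrow(x$maxima), nrow(x$labels), ncol(x$labels),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Probability mass (spreading) of each watershed region
#'
#' @param field the `height_field` that was segmented.
#' @param labels the corresponding `label_image`.
#' @return data.frame: `label`, `beta`, `chi` (the region's maximum),
#'   `spreading`; attribute `watershed_mass` holds the boundary-cell mass.
#' @export
label_spreading <- function(field, labels) {
  if (!identical(dim(field$grid), dim(labels$labels)))
    stop("field and label image have different shapes")
  area <- field$cell^2
  L <- nrow(labels$maxima)
  mass <- vapply(seq_len(L), function(l)
    sum(field$grid[labels$labels == l]) * area, numeric(1))
  out <- data.frame(label = seq_len(L),
                    beta = labels$maxima$beta, chi = labels$maxima$chi,
                    spreading = mass)
  attr(out, "watershed_mass") <- sum(field$grid[labels$labels == 0L]) * area
  out
}

#' Assign orientation records to watershed labels
#'
#' Each (beta, chi) point maps to its containing grid cell's label;
#' points in watershed cells take the nearest region (toroidal distance,
#' ties to the lower label id).
#'
#' @param records data.frame with `beta` and `chi` columns (degrees).
#' @param labels a `label_image`.
#' @return integer vector of label ids.
#' @export
assign_frames <- function(records, labels) {
  G <- nrow(labels$labels)
  cell <- labels$cell
  i <- pmin(G, floor(wrap360(records$beta) / cell) + 1L)
  j <- pmin(G, floor(wrap360(records$chi) / cell) + 1L)
  labels$filled[cbind(i, j)]
}

#' Relative populations of dimer configurations
#'
#' Fraction of assigned frames per label, optionally split by a grouping
#' factor (e.g. membrane composition). Groups with no assigned frames are
#' dropped with a warning.
#'
#' @param assignments integer label ids (from [assign_frames()]).
#' @param group optional grouping factor of the same length.
#' @return data.frame: `group` (if given), `label`, `n`, `population`;
#'   populations sum to 1 within each group.
#' @export
population_report <- function(assignments, group = NULL) {
  if (!length(assignments)) stop("no assigned frames")
  if (is.null(group)) group <- rep("all", length(assignments))
  out <- NULL
  for (g in unique(group)) {
    a <- assignments[group == g]
    if (!length(a)) {
      warning("group without assigned frames dropped: ", g)
      next
    }
    tab <- table(a)
    out <- rbind(out, data.frame(group = g,
                                 label = as.integer(names(tab)),
                                 n = as.integer(tab),
                                 population = as.numeric(tab) / length(a)))
  }
  out
}
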