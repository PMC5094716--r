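# Idealized rigid coarse-grained receptor template.
#
# The seven transmembrane helices are placed as vertical rods of backbone
# beads on a ring around the protein axis (z = membrane normal), each helix
# occupying a fixed angular sector. Going counterclockwise (viewed from the
# extracellular side, +z) the sector order follows the helix bundle:
# TM6, TM7, TM1, TM2, TM3, TM4, TM5, so that the TM5/TM6 sector boundary
# lies at azimuth 0. That boundary is the reference direction of the
# orientation analysis: two templates facing each other through their
# TM5/TM6 sectors form the symmetric TM5,6/TM5,6 dimer with beta = chi = 0.

helix_sector_order <- c("TM6", "TM7", "TM1", "TM2", "TM3", "TM4", "TM5")

#' Azimuthal sector centers of the template helices
#'
#' @param helix_names helix names present in the template.
#' @return named numeric vector of sector-center azimuths in degrees.
#' @export
helix_sector_centers <- function(helix_names = helix_sector_order) {
  w <- 360 / length(helix_sector_order)
  centers <- wrap360(w * (seq_along(helix_sector_order) - 0.5))
  names(centers) <- helix_sector_order
  centers[helix_names[helix_names %in% names(centers)]]
}

#' Build a rigid receptor template
#'
#' One backbone bead per transmembrane residue. Helix `h` is a vertical rod
#' at the ring radius, at its sector-center azimuth, with its residues'
#' beads evenly stacked along z across the membrane span. The template's
#' center of mass is at the origin, its principal axis is z, and its
#' reference x direction (azimuth 0) points through the TM5/TM6 sector
#' boundary, which makes the relative-orientation angles interpretable as
#' helix-helix interfaces.
#'
#' @param helix_ranges named list of inclusive residue intervals
#'   (default [cxcr4_helix_ranges()]). Must contain seven helices.
#' @param radius ring radius in nm.
#' @param height membrane-spanning extent of the rods in nm.
#' @return object of class `cg_template` with elements `coords` (n x 3),
#'   `residue_number`, `helix` (per bead), `sector_centers`, `radius`,
#'   `height`, and `r_circ` (circumscribed-sphere radius).
#' @export
build_protein_template <- function(helix_ranges = cxcr4_helix_ranges(),
                                   radius = 1.2, height = 3.0) {
  if (length(helix_ranges) != 7)
    stop("seven helix ranges are required")
  centers <- helix_sector_centers(names(helix_ranges))
  if (length(centers) != 7)
    stop("helix ranges must be named TM1..TM7")
  coords <- NULL; resno <- integer(0); helix <- character(0)
  for (h in names(helix_ranges)) {
    r <- helix_ranges[[h]]
    res <- seq.int(r[1], r[2])
    n <- length(res)
    az <- centers[[h]] * pi / 180
    z <- -height / 2 + (seq_len(n) - 0.5) * height / n
    coords <- rbind(coords, cbind(radius * cos(az), radius * sin(az), z))
    resno <- c(resno, res)
    helix <- c(helix, rep(h, n))
  }
  # order beads by residue number (topology invariant: ascending residues)
  ord <- order(resno)
  coords <- coords[ord, , drop = FALSE]
  dimnames(coords) <- NULL
  coords <- sweep(coords, 2, colMeans(coords))
  helix <- helix[ord]; resno <- sort(resno)
  # align the template with the orientation-analysis convention exactly:
  # the mean direction of the TM5/TM6 beads (the internal-frame +x
  # reference) is rotated onto azimuth 0. With unequal helix lengths the
  # bead-count-weighted mean would otherwise sit a fraction of a degree
  # off the geometric sector boundary.
  v <- colMeans(coords[helix %in% c("TM5", "TM6"), , drop = FALSE])
  coords <- rotate_z(coords, -atan2(v[2], v[1]) * 180 / pi)
  structure(list(coords = coords, residue_number = resno,
                 helix = helix, sector_centers = centers,
                 radius = radius, height = height,
                 r_circ = max(sqrt(rowSums(coords^2)))),
            class = "cg_template")
}

#' @export
print.cg_template <- function(x, ...) {
  cat(sprintf("cg_template: %d beads, ring radius %.2f nm, height %.2f nm\n",
              nrow(x$coords), x$radius, x$height))
  invisible(x)
}

#' World coordinates of a placed template instance
#'
#' z-rotation (degrees) followed by translation of the center to `origin`.
#'
#' @param template a `cg_template`.
#' @param origin length-2 (xy) or length-3 position, nm.
#' @param zrot rotation about z in degrees.
#' @return n x 3 coordinate matrix.
#' @export
place_template <- function(template, origin, zrot) {
  if (length(origin) == 2) origin <- c(origin, 0)
  sweep(rotate_z(template$coords, zrot), 2, -origin)
}

#' Contact center distance for a relative dimer configuration
#'
#' Center-to-center distance at which two template instances in the
#' relative configuration (beta, chi) have their closest bead pair exactly
#' at `target_gap` nm. With B displaced by d*u from A, each pair's distance
#' is sqrt(d^2 - 2 d (c.u) + |c|^2) with c = a_i - b_j, so the required d
#' is the largest positive root over all pairs (closed form).
#'
#' @param template a `cg_template`.
#' @param beta,chi relative-orientation angles in degrees.
#' @param target_gap closest-pair distance, nm (default 0.5).
#' @return center distance in nm.
#' @export
contact_distance <- function(template, beta = 0, chi = 0, target_gap = 0.5) {
  phi <- (180 + beta - chi) %% 360
  A <- template$coords
  B <- rotate_z(template$coords, phi)
  u <- c(cos(beta * pi / 180), sin(beta * pi / 180), 0)
  cx <- outer(A[, 1], B[, 1], "-")
  cy <- outer(A[, 2], B[, 2], "-")
  cz <- outer(A[, 3], B[, 3], "-")
  s <- cx * u[1] + cy * u[2]          # u has no z component
  nc2 <- cx * cx + cy * cy + cz * cz
  disc <- s * s - nc2 + target_gap^2
  ok <- disc >= 0
  if (!any(ok)) return(2 * template$r_circ + target_gap)
  max(s[ok] + sqrt(disc[ok]))
}
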