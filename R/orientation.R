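# Internal coordinate frames of the receptors and the relative-orientation
# angles beta (partner position), phi (partner self-rotation, "phase") and
# chi = (180 + beta - phi) mod 360 (the angle under which the partner sees
# the reference), plus helix tilt angles.
#
# Convention (fixed by the symmetric TM5,6/TM5,6 anchor configuration,
# which must yield beta = chi = 0): z is the membrane normal pointing to
# the extracellular side; x points from the protein's center of mass
# through its TM5/TM6 sector; y completes a right-handed triad. Angles
# increase counterclockwise viewed from +z.

#' Internal coordinate frame of a receptor
#'
#' @param coords n x 3 matrix of the TM-domain backbone bead positions, nm.
#' @param ref_idx indices (into `coords`) of the beads whose mean direction
#'   from the center of mass defines +x: the TM5 and TM6 beads.
#' @param membrane_normal membrane normal (default +z).
#' @return object of class `internal_frame`: list with `origin` and the
#'   orthonormal `x`, `y`, `z` axes.
#' @export
internal_frame <- function(coords, ref_idx,
                           membrane_normal = c(0, 0, 1)) {
  if (nrow(coords) < 3) stop("need at least 3 beads")
  origin <- colMeans(coords)
  centered <- sweep(coords, 2, origin)
  if (max(svd(centered, nu = 0, nv = 0)$d) < 1e-9)
    stop("degenerate coordinates")
  z <- normalize(membrane_normal)
  v <- colMeans(coords[ref_idx, , drop = FALSE]) - origin
  v <- v - sum(v * z) * z
  if (vnorm(v) < 1e-9)
    stop("reference beads are collinear with the membrane normal")
  x <- normalize(v)
  y <- cross3(z, x)
  structure(list(origin = origin, x = x, y = y, z = z),
            class = "internal_frame")
}

#' Internal frames of the two receptors in a trajectory frame
#'
#' @param frame a `cg_frame`.
#' @param topology matching `cg_topology`.
#' @param molecules the two protein molecule ids (default 1 and 2).
#' @return list of two `internal_frame`s.
#' @export
protein_frames <- function(frame, topology, molecules = c(1L, 2L)) {
  lapply(molecules, function(m) {
    tm <- tm_beads(topology, m)
    ref <- select_beads(topology, molecule = m, helices = c("TM5", "TM6"))
    internal_frame(unwrap_molecule(frame$coordinates[tm, , drop = FALSE],
                                   frame$box),
                   match(ref, tm))
  })
}

#' Relative orientation of two receptors
#'
#' beta is the azimuth of B's origin in A's frame, phi the rotation of B's
#' x-axis relative to A's (about z), and chi = (180 + beta - phi) mod 360.
#' The center-of-mass distance uses the minimum image.
#'
#' @param frame_A,frame_B `internal_frame`s of the reference (A) and
#'   partner (B) receptor.
#' @param box periodic box `c(Lx, Ly, Lz)` nm.
#' @return one-row data.frame: `beta`, `phi`, `chi` (degrees, in
#'   `[0, 360)`), `com_distance` (nm).
#' @export
relative_orientation <- function(frame_A, frame_B, box) {
  r <- drop(minimum_image(frame_A$origin, frame_B$origin, box))
  d <- vnorm(r)
  if (d < 1e-9) stop("coincident receptor origins")
  beta <- wrap360(atan2(sum(r * frame_A$y), sum(r * frame_A$x)) * 180 / pi)
  phi <- wrap360(atan2(sum(frame_B$x * frame_A$y),
                       sum(frame_B$x * frame_A$x)) * 180 / pi)
  chi <- wrap360(180 + beta - phi)
  data.frame(beta = beta, phi = phi, chi = chi, com_distance = d)
}

#' Per-frame orientation records for a run
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param frames frame indices (default all).
#' @return data.frame: `time`, `beta`, `phi`, `chi`, `com_distance`.
#' @export
orientation_series <- function(run, topology, frames = seq_along(run$times)) {
  tmA <- tm_beads(topology, 1L); tmB <- tm_beads(topology, 2L)
  refA <- match(select_beads(topology, molecule = 1L,
                             helices = c("TM5", "TM6")), tmA)
  refB <- match(select_beads(topology, molecule = 2L,
                             helices = c("TM5", "TM6")), tmB)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    i <- frames[k]
    fr <- get_frame(run, i)
    fA <- internal_frame(unwrap_molecule(fr$coordinates[tmA, , drop = FALSE],
                                         fr$box), refA)
    fB <- internal_frame(unwrap_molecule(fr$coordinates[tmB, , drop = FALSE],
                                         fr$box), refB)
    rec <- relative_orientation(fA, fB, fr$box)
    rec$time <- fr$time
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  res[, c("time", "beta", "phi", "chi", "com_distance")]
}

#' Orientation sample of a dimer over the final window
#'
#' Restricts the orientation records to the last `window` ns of a run that
#' is bound at its final frame; runs that end unbound are excluded (NULL).
#' A run shorter than the window contributes all its bound frames and is
#' flagged truncated.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param timeline the run's `binding_timeline`.
#' @param window window length in ns (default 50).
#' @return data.frame of orientation records with attribute `truncated`,
#'   or NULL for runs unbound at the end.
#' @export
dimer_angle_sample <- function(run, topology, timeline, window = 50) {
  n <- length(run$times)
  if (!timeline$bound[n]) return(NULL)
  t_end <- run$times[n]
  truncated <- (t_end - run$times[1]) < window
  sel <- which(run$times > t_end - window & timeline$bound)
  rec <- orientation_series(run, topology, frames = sel)
  attr(rec, "truncated") <- truncated
  rec
}

#' Tilt of a helix segment
#'
#' Angle between the dominant principal axis of the segment's bead
#' coordinates and the membrane normal, folded into `[0, 90]` degrees.
#'
#' @param coords n x 3 matrix of segment bead positions (n >= 3), nm.
#' @param membrane_normal membrane normal (default +z).
#' @return tilt angle in degrees.
#' @export
helix_tilt <- function(coords, membrane_normal = c(0, 0, 1)) {
  if (nrow(coords) < 3) stop("need at least 3 beads")
  centered <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centered, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9) stop("degenerate segment")
  axis <- sv$v[, 1]
  n <- normalize(membrane_normal)
  acos(pmin(1, abs(sum(axis * n)))) * 180 / pi
}

#' TM5 tilt time series
#'
#' Tilt of the upper and lower TM5 sub-segments relative to the membrane
#' normal, per frame and per receptor.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param molecule protein molecule id.
#' @param upper,lower residue ranges of the two sub-segments (defaults
#'   193-205 and 206-227).
#' @return data.frame: `time`, `tilt_upper`, `tilt_lower` (degrees).
#' @export
tm5_tilt_series <- function(run, topology, molecule = 1L,
                            upper = 193:205, lower = 206:227) {
  iu <- select_beads(topology, molecule = molecule, residues = upper)
  il <- select_beads(topology, molecule = molecule, residues = lower)
  n <- length(run$times)
  tu <- numeric(n); tl <- numeric(n)
  for (i in seq_len(n)) {
    fr <- get_frame(run, i)
    tu[i] <- helix_tilt(unwrap_molecule(fr$coordinates[iu, , drop = FALSE],
                                        fr$box))
    tl[i] <- helix_tilt(unwrap_molecule(fr$coordinates[il, , drop = FALSE],
                                        fr$box))
  }
  data.frame(time = run$times, tilt_upper = tu, tilt_lower = tl)
}
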