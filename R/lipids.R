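# Cholesterol-receptor contact statistics and bilayer thickness.

#' Cholesterol molecules bound to a protein
#'
#' A cholesterol is bound when any of its beads lies within `cutoff`
#' (minimum image) of any protein bead — the first-solvation-shell
#' criterion.
#'
#' @param frame a `cg_frame`.
#' @param protein_beads protein bead indices.
#' @param topology matching `cg_topology`.
#' @param cutoff contact distance in nm (default 0.62).
#' @return integer vector of bound cholesterol molecule ids.
#' @export
cholesterol_bound <- function(frame, protein_beads, topology,
                              cutoff = 0.62) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  b <- topology$beads
  chol_rows <- which(b$species == "CHOL")
  if (!length(chol_rows)) return(integer(0))
  P <- frame$coordinates[protein_beads, , drop = FALSE]
  C <- frame$coordinates[chol_rows, , drop = FALSE]
  d <- pair_distances(C, P, frame$box)
  close_bead <- apply(d, 1, min) < cutoff
  sort(unique(b$molecule_id[chol_rows][close_bead]))
}

#' Per-residue cholesterol occupancy and contact times
#'
#' For every residue of a protein: occupancy is the fraction of window
#' frames with at least one cholesterol bead within the cutoff of any bead
#' of that residue; the mean contact time averages the lengths of maximal
#' contiguous contact intervals (a contact ends at the first frame without
#' any cholesterol in range — no gap tolerance unless `gap_tolerance` > 0
#' frames).
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param molecule protein molecule id (default 1).
#' @param window analysis window `c(start, end)` in ns (default
#'   `c(200, 1000)`, discarding initial construction-biased contacts).
#' @param cutoff contact distance, nm (default 0.62).
#' @param gap_tolerance number of contact-free frames tolerated inside one
#'   contact interval (default 0).
#' @return data.frame of class `occupancy_profile`: `residue_number`,
#'   `residue_name`, `occupancy`, `mean_contact_ns`.
#' @export
residue_occupancy <- function(run, topology, molecule = 1L,
                              window = c(200, 1000), cutoff = 0.62,
                              gap_tolerance = 0L) {
  sel <- which(run$times >= window[1] & run$times <= window[2])
  if (!length(sel))
    stop("analysis window lies outside the run")
  b <- topology$beads
  prot_rows <- which(b$molecule_id == molecule)
  if (!length(prot_rows)) stop("no beads for molecule ", molecule)
  chol_rows <- which(b$species == "CHOL")
  res <- unique(b$residue_number[prot_rows])
  contact <- matrix(FALSE, length(sel), length(res))
  if (length(chol_rows)) {
    res_of_row <- match(b$residue_number[prot_rows], res)
    for (k in seq_along(sel)) {
      fr <- get_frame(run, sel[k])
      d <- pair_distances(fr$coordinates[chol_rows, , drop = FALSE],
                          fr$coordinates[prot_rows, , drop = FALSE],
                          fr$box)
      close_any <- apply(d < cutoff, 2, any)   # per protein bead
      contact[k, ] <- vapply(seq_along(res), function(r)
        any(close_any[res_of_row == r]), logical(1))
    }
  }
  stride <- if (length(sel) > 1) diff(run$times[sel])[1] else 0
  occ <- colMeans(contact)
  mct <- vapply(seq_along(res), function(r)
    mean_contact_time(contact[, r], stride, gap_tolerance), numeric(1))
  name <- b$residue_name[prot_rows][match(res, b$residue_number[prot_rows])]
  structure(data.frame(residue_number = res, residue_name = name,
                       occupancy = occ, mean_contact_ns = mct),
            class = c("occupancy_profile", "data.frame"),
            window = window)
}

# average length (ns) of maximal contiguous TRUE intervals; 0 if none
mean_contact_time <- function(flags, stride, gap_tolerance = 0L) {
  if (gap_tolerance > 0L) {
    # close gaps of up to gap_tolerance FALSE frames between contacts
    r <- rle(flags)
    short_gap <- !r$values & r$lengths <= gap_tolerance
    inner <- seq_along(r$values)[-c(1, length(r$values))]
    r$values[intersect(which(short_gap), inner)] <- TRUE
    flags <- inverse.rle(r)
  }
  r <- rle(flags)
  len <- r$lengths[r$values]
  if (!length(len)) return(0)
  mean(len) * stride
}

#' Cholesterols intercalated at the dimer interface
#'
#' Number of cholesterol molecules simultaneously bound (per
#' [cholesterol_bound()]) to both receptors in one frame.
#'
#' @param frame a `cg_frame`.
#' @param beads_A,beads_B disjoint protein bead sets.
#' @param topology matching `cg_topology`.
#' @param cutoff contact distance, nm (default 0.62).
#' @return integer count.
#' @export
intercalation_count <- function(frame, beads_A, beads_B, topology,
                                cutoff = 0.62) {
  if (length(intersect(beads_A, beads_B)))
    stop("protein bead sets must be disjoint")
  bothA <- cholesterol_bound(frame, beads_A, topology, cutoff)
  bothB <- cholesterol_bound(frame, beads_B, topology, cutoff)
  length(intersect(bothA, bothB))
}

#' Interface intercalation statistics over the final window
#'
#' Per-frame intercalation counts over the last `window` ns of a run and
#' the probability of finding at least one interfacial cholesterol there.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param window final analysis window, ns (default 50).
#' @param cutoff contact distance, nm.
#' @return list with `counts` (data.frame time, count) and
#'   `p_at_least_one`.
#' @export
intercalation_report <- function(run, topology, window = 50, cutoff = 0.62) {
  t_end <- run$times[length(run$times)]
  sel <- which(run$times > t_end - window)
  bA <- select_beads(topology, molecule = 1L)
  bB <- select_beads(topology, molecule = 2L)
  counts <- vapply(sel, function(i)
    intercalation_count(get_frame(run, i), bA, bB, topology, cutoff),
    integer(1))
  list(counts = data.frame(time = run$times[sel], count = counts),
       p_at_least_one = mean(counts >= 1))
}

#' Global bilayer thickness from the reference-bead density profile
#'
#' Histogram of the reference beads' z coordinates (bin 0.02 nm, 3-bin
#' running mean), pooled over frames; the thickness is the distance
#' between the density maxima of the upper and lower leaflet (split at the
#' reference beads' mean z).
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param reference_bead reference bead name (default `"PO4"`; use
#'   `"GL1"` for a monoacylglycerol membrane).
#' @param bin bin width in nm (default 0.02).
#' @return thickness in nm.
#' @export
bilayer_thickness <- function(run, topology, reference_bead = "PO4",
                              bin = 0.02) {
  rows <- which(topology$beads$bead_name == reference_bead)
  if (!length(rows)) stop("no beads named ", reference_bead)
  z <- as.vector(run$coords[rows, 3, ])
  mid <- mean(z)
  if (diff(range(z)) < 4 * bin)
    stop("unimodal reference-bead profile: leaflets indistinguishable")
  breaks <- seq(min(z) - bin, max(z) + bin, bin)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  dens <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  dens[is.na(dens)] <- h$counts[is.na(dens)]
  centers <- h$mids
  up <- centers > mid
  if (!any(up) || all(up))
    stop("unimodal reference-bead profile: leaflets indistinguishable")
  z_up <- centers[up][which.max(dens[up])]
  z_lo <- centers[!up][which.max(dens[!up])]
  if (abs(z_up - z_lo) < 2 * bin)
    stop("unimodal reference-bead profile: leaflets indistinguishable")
  z_up - z_lo
}

#' Bilayer thickness in the vicinity of the protein
#'
#' Per frame: mean z of upper-leaflet reference beads within `radius` of
#' any protein bead minus the same for the lower leaflet; averaged over
#' frames. Frames without qualifying lipids in both leaflets are skipped;
#' if none qualify the result is NA with a warning.
#'
#' @param run a `cg_run`.
#' @param topology matching `cg_topology`.
#' @param protein_beads protein bead indices (default: both receptors).
#' @param radius qualifying distance to the protein, nm (default 1).
#' @param reference_bead reference bead name (default `"PO4"`).
#' @return mean local thickness in nm (NA if no frame qualifies).
#' @export
local_thickness <- function(run, topology,
                            protein_beads = which(topology$beads$species ==
                                                    "protein"),
                            radius = 1, reference_bead = "PO4") {
  if (!length(protein_beads)) stop("no protein beads given")
  rows <- which(topology$beads$bead_name == reference_bead)
  if (!length(rows)) stop("no beads named ", reference_bead)
  vals <- numeric(0)
  for (i in seq_along(run$times)) {
    fr <- get_frame(run, i)
    P <- fr$coordinates[protein_beads, , drop = FALSE]
    Lp <- fr$coordinates[rows, , drop = FALSE]
    d <- pair_distances(Lp, P, fr$box)
    near <- apply(d, 1, min) < radius
    if (!any(near)) next
    z <- Lp[near, 3]
    mid <- mean(fr$coordinates[protein_beads, 3])
    up <- z > mid
    if (!any(up) || all(up)) next
    vals <- c(vals, mean(z[up]) - mean(z[!up]))
  }
  if (!length(vals)) {
    warning("no frame with qualifying lipids in both leaflets")
    return(NA_real_)
  }
  mean(vals)
}
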