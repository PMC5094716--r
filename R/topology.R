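# Domain containers: system topology, trajectory frames, ensemble runs,
# and the periodic-geometry primitives every analysis stage relies on.

#' Transmembrane helix residue ranges of CXCR4
#'
#' Inclusive residue intervals of the seven transmembrane helices of the
#' chemokine receptor type 4, in the receptor's 1-based sequence numbering
#' (TM1 Ala34-Gly64 through TM7 Cys274-Leu301).
#'
#' @return named list `TM1` .. `TM7` of length-2 integer vectors
#'   `c(first, last)`.
#' @export
cxcr4_helix_ranges <- function() {
  list(TM1 = c(34L, 64L), TM2 = c(72L, 100L), TM3 = c(106L, 139L),
       TM4 = c(145L, 174L), TM5 = c(193L, 227L), TM6 = c(238L, 267L),
       TM7 = c(274L, 301L))
}

#' Construct a system topology
#'
#' A topology is the static description of a coarse-grained system: one row
#' per bead (molecule id, species, bead name, residue number/name, non-bonded
#' type key, charge), the transmembrane helix residue intervals, and the
#' symmetric non-bonded parameter table.
#'
#' @param beads data.frame with columns `bead_id`, `bead_name`,
#'   `residue_number`, `residue_name`, `molecule_id`, `species`, `type_key`,
#'   `charge`. Species must be one of `protein`, `POPC`, `CHOL`, `DEPC`,
#'   `GMO`, `water`.
#' @param helix_ranges named list of inclusive residue intervals, see
#'   [cxcr4_helix_ranges()].
#' @param nonbonded data.frame with columns `type_i`, `type_j`, `C6`
#'   (kJ/mol nm^6) and `C12` (kJ/mol nm^12). Pairs are stored symmetrically.
#' @return object of class `cg_topology`.
#' @export
topology <- function(beads, helix_ranges = cxcr4_helix_ranges(),
                     nonbonded = NULL) {
  required <- c("bead_id", "bead_name", "residue_number", "residue_name",
                "molecule_id", "species", "type_key", "charge")
  missing <- setdiff(required, names(beads))
  if (length(missing))
    stop("beads table lacks columns: ", paste(missing, collapse = ", "))
  species_ok <- c("protein", "POPC", "CHOL", "DEPC", "GMO", "water")
  bad <- setdiff(unique(beads$species), species_ok)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))

  # helix ranges must be disjoint and ascending
  rng <- do.call(rbind, helix_ranges)
  if (any(rng[, 1] > rng[, 2])) stop("helix range with first > last")
  ord <- order(rng[, 1])
  if (any(diff(ord) < 0) || any(rng[ord[-1], 1] <= rng[ord[-nrow(rng)], 2]))
    stop("helix ranges must be disjoint and ascending")

  if (!is.null(nonbonded)) {
    # store symmetrically, keyed "i|j" with i <= j lexicographically
    key <- nb_key(nonbonded$type_i, nonbonded$type_j)
    if (anyDuplicated(key)) {
      dup <- nonbonded[duplicated(key) | duplicated(key, fromLast = TRUE), ]
      agg6 <- tapply(nonbonded$C6, key, function(x) diff(range(x)))
      agg12 <- tapply(nonbonded$C12, key, function(x) diff(range(x)))
      if (any(agg6 > 1e-12) || any(agg12 > 1e-12))
        stop("nonbonded table is not symmetric")
      keep <- !duplicated(key)
      nonbonded <- nonbonded[keep, ]
      key <- key[keep]
    }
    nonbonded <- data.frame(key = key, C6 = nonbonded$C6, C12 = nonbonded$C12,
                            stringsAsFactors = FALSE)
  }

  structure(list(beads = beads, helix_ranges = helix_ranges,
                 nonbonded = nonbonded),
            class = "cg_topology")
}

nb_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$beads), "beads,",
      length(unique(x$beads$molecule_id)), "molecules\n")
  cat("species:", paste(sort(unique(x$beads$species)), collapse = ", "), "\n")
  invisible(x)
}

#' Look up C6/C12 parameters for bead type pairs
#'
#' @param topology a `cg_topology` with a non-bonded table.
#' @param type_i,type_j character vectors of type keys (recycled).
#' @return data.frame with columns `C6`, `C12`.
#' @export
nonbonded_params <- function(topology, type_i, type_j) {
  if (is.null(topology$nonbonded)) stop("topology has no nonbonded table")
  key <- nb_key(type_i, type_j)
  idx <- match(key, topology$nonbonded$key)
  if (anyNA(idx))
    stop("missing nonbonded parameters for type pair(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  topology$nonbonded[idx, c("C6", "C12")]
}

#' Construct a trajectory frame
#'
#' @param time time stamp in ns.
#' @param coordinates n x 3 matrix of bead positions in nm.
#' @param box rectangular box edge lengths `c(Lx, Ly, Lz)` in nm.
#' @return object of class `cg_frame`.
#' @export
trajectory_frame <- function(time, coordinates, box) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be an n x 3 matrix")
  if (!all(is.finite(coordinates))) stop("non-finite coordinates")
  if (length(box) != 3 || any(box <= 0)) stop("box lengths must be > 0")
  structure(list(time = time, coordinates = coordinates, box = as.numeric(box)),
            class = "cg_frame")
}

#' Construct an ensemble run
#'
#' One simulation's time-ordered frame sequence. Coordinates are stored as a
#' beads x 3 x frames array with a constant rectangular box.
#'
#' @param run_id identifier.
#' @param times strictly increasing frame times, ns.
#' @param coords array `dim = c(n_beads, 3, n_frames)`, nm.
#' @param box `c(Lx, Ly, Lz)` nm.
#' @param metadata list; conventionally holds `composition` and
#'   `cholesterol_fraction`.
#' @return object of class `cg_run`.
#' @export
ensemble_run <- function(run_id, times, coords, box, metadata = list()) {
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_beads x 3 x n_frames array")
  if (dim(coords)[3] != length(times))
    stop("number of frames disagrees with length(times)")
  structure(list(run_id = run_id, times = times, coords = coords,
                 box = as.numeric(box), metadata = metadata),
            class = "cg_run")
}

#' Extract one frame from a run
#'
#' @param run a `cg_run`.
#' @param i frame index.
#' @return a `cg_frame`.
#' @export
get_frame <- function(run, i) {
  trajectory_frame(run$times[i], run$coords[, , i, drop = TRUE], run$box)
}

#' @export
print.cg_run <- function(x, ...) {
  cat(sprintf("cg_run '%s': %d beads, %d frames, %.4g-%.4g ns\n",
              as.character(x$run_id), dim(x$coords)[1], length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Periodic geometry

#' Minimum-image displacement vectors
#'
#' Componentwise displacement `b - a` wrapped into `(-L/2, L/2]` for a
#' rectangular periodic box.
#'
#' @param a,b n x 3 matrices (or length-3 vectors) of positions in nm.
#' @param box `c(Lx, Ly, Lz)` nm.
#' @return n x 3 matrix of minimum-image displacements.
#' @export
minimum_image <- function(a, b, box) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- b - a
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Minimum-image distance
#'
#' Smallest distance between `a` and `b` over all periodic images of a
#' rectangular box.
#'
#' @param a,b positions (length-3 vectors or n x 3 matrices), nm.
#' @param box `c(Lx, Ly, Lz)` nm; all entries must be positive.
#' @return distances in nm.
#' @export
minimum_image_distance <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be > 0")
  d <- minimum_image(a, b, box)
  sqrt(rowSums(d^2))
}

# All pairwise minimum-image distances between two coordinate sets.
# Returns an nA x nB matrix. Used by the energy and lipid-contact stages.
pair_distances <- function(A, B, box) {
  nA <- nrow(A); nB <- nrow(B)
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Select beads from a topology
#'
#' Deterministic, order-stable bead selection. All given criteria are
#' combined with AND; vectors within a criterion are OR.
#'
#' @param topology a `cg_topology`.
#' @param molecule molecule id(s), or NULL.
#' @param species species name(s) (e.g. `"protein"`, `"CHOL"`), or NULL.
#' @param residues residue numbers, or NULL.
#' @param helices helix names (e.g. `c("TM1", "TM5")`) resolved through the
#'   topology's helix ranges, or NULL. Combined with `residues` by union.
#' @param bead_names bead name(s) (e.g. `"PO4"`, `"ROH"`), or NULL.
#' @return increasing integer vector of bead row indices.
#' @export
select_beads <- function(topology, molecule = NULL, species = NULL,
                         residues = NULL, helices = NULL, bead_names = NULL) {
  b <- topology$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(molecule)) {
    if (!all(molecule %in% b$molecule_id))
      stop("unknown molecule id(s): ",
           paste(setdiff(molecule, b$molecule_id), collapse = ", "))
    keep <- keep & b$molecule_id %in% molecule
  }
  if (!is.null(species)) {
    if (!all(species %in% b$species))
      stop("no beads of species: ",
           paste(setdiff(species, b$species), collapse = ", "))
    keep <- keep & b$species %in% species
  }
  res <- residues
  if (!is.null(helices)) {
    if (!all(helices %in% names(topology$helix_ranges)))
      stop("unknown helix name(s): ",
           paste(setdiff(helices, names(topology$helix_ranges)),
                 collapse = ", "))
    for (h in helices) {
      r <- topology$helix_ranges[[h]]
      res <- c(res, seq.int(r[1], r[2]))
    }
  }
  if (!is.null(res)) keep <- keep & b$residue_number %in% res
  if (!is.null(bead_names)) {
    if (!all(bead_names %in% b$bead_name))
      stop("unknown bead name(s): ",
           paste(setdiff(bead_names, b$bead_name), collapse = ", "))
    keep <- keep & b$bead_name %in% bead_names
  }
  which(keep)
}

#' All transmembrane-domain beads of one molecule
#'
#' Union of the TM1..TM7 residue intervals, the bead set the dimerization
#' criterion is evaluated on.
#'
#' @param topology a `cg_topology`.
#' @param molecule molecule id.
#' @return integer vector of bead indices.
#' @export
tm_beads <- function(topology, molecule) {
  select_beads(topology, molecule = molecule,
               helices = names(topology$helix_ranges))
}
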