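# Fixed-column GRO coordinate I/O. Layout per frame:
#   title line (with "t= <time>" convention for trajectories)
#   atom count
#   one record per atom: %5d%-5s%5s%5d%8.3f%8.3f%8.3f (resnum, resname,
#     atomname, atomnum, x, y, z in nm); optional velocity columns ignored
#   box line: three floats (rectangular); a box line with more than three
#     non-zero entries (triclinic/rhombic) is rejected.

parse_gro_frame <- function(lines, offset, path) {
  title <- lines[offset]
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 1])))
  if (is.na(natoms) || natoms < 1)
    stop(sprintf("%s: malformed atom count at line %d", path, offset + 1))
  need <- offset + 1 + natoms + 1
  if (need > length(lines))
    stop(sprintf(
      "%s: header count %d at line %d disagrees with records (file truncated)",
      path, natoms, offset + 1))
  rec <- lines[(offset + 2):(offset + 1 + natoms)]
  if (any(nchar(rec) < 44))
    stop(sprintf("%s: malformed column widths at line %d", path,
                 offset + 1 + which(nchar(rec) < 44)[1]))
  resnum <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  atomname <- trimws(substr(rec, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(resnum) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("%s: malformed atom record at line %d", path,
                 offset + 1 + bad[1]))
  boxline <- lines[offset + 1 + natoms + 1]
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(boxline), "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop(sprintf("%s: malformed box line at line %d", path,
                 offset + 1 + natoms + 1))
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop(sprintf("%s: non-rectangular (triclinic) box is not supported", path))
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(title = title, time = time,
       beads = data.frame(residue_number = resnum, residue_name = resname,
                          bead_name = atomname, stringsAsFactors = FALSE),
       coordinates = cbind(x = x, y = y, z = z),
       box = boxv[1:3],
       next_offset = offset + natoms + 3)
}

#' Read a GRO coordinate file
#'
#' Parses the first frame of a fixed-column GRO file into a topology
#' skeleton (residue numbers/names and bead names; species, charges and
#' non-bonded parameters are not stored in GRO) and a trajectory frame.
#'
#' @param path file path.
#' @return list with elements `beads` (data.frame: residue_number,
#'   residue_name, bead_name), `frame` (a `cg_frame`) and `title`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop(sprintf("%s: not a GRO file (too short)", path))
  p <- parse_gro_frame(lines, 1L, path)
  time <- if (is.na(p$time)) 0 else p$time
  list(beads = p$beads,
       frame = trajectory_frame(time, p$coordinates, p$box),
       title = p$title)
}

#' Read a multi-frame GRO trajectory
#'
#' Concatenated GRO frames (the conventional multi-frame layout) are parsed
#' into an ensemble run. The bead count must be constant across frames.
#'
#' @param path file path.
#' @param run_id identifier for the resulting run.
#' @param metadata metadata list passed to [ensemble_run()].
#' @return list with `run` (a `cg_run`) and `beads` (topology skeleton from
#'   the first frame).
#' @export
read_gro_trajectory <- function(path, run_id = path, metadata = list()) {
  lines <- readLines(path)
  frames <- list(); offset <- 1L; i <- 0L
  while (offset <= length(lines) && nzchar(trimws(lines[offset]))) {
    i <- i + 1L
    frames[[i]] <- parse_gro_frame(lines, offset, path)
    offset <- frames[[i]]$next_offset
  }
  if (!length(frames)) stop(sprintf("%s: no frames found", path))
  n <- nrow(frames[[1]]$beads)
  if (any(vapply(frames, function(f) nrow(f$beads), 0L) != n))
    stop(sprintf("%s: bead count varies across frames", path))
  times <- vapply(frames, function(f) f$time, 0)
  if (anyNA(times)) times <- seq_along(frames) - 1
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (j in seq_along(frames)) coords[, , j] <- frames[[j]]$coordinates
  list(run = ensemble_run(run_id, times, coords, frames[[1]]$box, metadata),
       beads = frames[[1]]$beads)
}

#' Write a GRO coordinate file
#'
#' Writes one or more frames in fixed-column GRO layout at the format's
#' native 3-decimal (pm) coordinate precision.
#'
#' @param path output file path.
#' @param beads data.frame with `residue_number`, `residue_name`,
#'   `bead_name` (a topology skeleton or a `cg_topology`'s beads table).
#' @param frames a `cg_frame`, a list of them, or a `cg_run`.
#' @param title title-line prefix; the frame time is appended as `t= <ns>`.
#' @return `path`, invisibly.
#' @export
write_gro <- function(path, beads, frames, title = "cgdimer system") {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  if (inherits(frames, "cg_run")) {
    run <- frames
    frames <- lapply(seq_along(run$times), function(i) get_frame(run, i))
  }
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(beads)
  atomnum <- ((seq_len(n) - 1L) %% 99999L) + 1L
  resnum <- ((beads$residue_number - 1L) %% 99999L) + 1L
  for (fr in frames) {
    stopifnot(nrow(fr$coordinates) == n)
    writeLines(sprintf("%s t= %.6f", title, fr$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resnum, substr(beads$residue_name, 1, 5),
                       substr(beads$bead_name, 1, 5), atomnum,
                       fr$coordinates[, 1], fr$coordinates[, 2],
                       fr$coordinates[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}
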