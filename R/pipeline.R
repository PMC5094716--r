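# Ensemble-scale orchestration: synthesize ensembles to disk, read them
# back through a manifest, run all analysis stages in dependency order and
# write tab-separated reports.

#' Volume of the protein-lipid double layer (approximation)
#'
#' Box area times bilayer thickness. The reference analysis treats the
#' double-layer volume as an input; this helper is a clearly labelled
#' approximation for synthetic boxes.
#'
#' @param box `c(Lx, Ly, Lz)` nm.
#' @param thickness bilayer thickness, nm.
#' @return volume in nm^3.
#' @export
double_layer_volume <- function(box, thickness) {
  box[1] * box[2] * thickness
}

#' Write a synthetic ensemble to disk
#'
#' One multi-frame GRO trajectory per run, a tab-separated manifest
#' (run_id, path, composition, cholesterol_fraction), the topology tables,
#' and the ground-truth event records.
#'
#' @param ensemble result of [simulate_ensemble()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  topo <- ensemble$topology
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(topo$beads, "topology_beads.tsv")
  nb <- topo$nonbonded
  parts <- do.call(rbind, strsplit(nb$key, "|", fixed = TRUE))
  tsv(data.frame(type_i = parts[, 1], type_j = parts[, 2],
                 C6 = nb$C6, C12 = nb$C12), "nonbonded.tsv")
  hr <- do.call(rbind, lapply(names(topo$helix_ranges), function(h)
    data.frame(helix = h, first = topo$helix_ranges[[h]][1],
               last = topo$helix_ranges[[h]][2])))
  tsv(hr, "helix_ranges.tsv")
  man <- NULL
  for (i in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[i]]
    path <- sprintf("run_%04d.gro", run$run_id)
    write_gro(file.path(dir, path), topo$beads, run)
    ev <- ensemble$truth[[i]]$events
    if (nrow(ev))
      tsv(ev, file.path("truth", sprintf("run_%04d_events.tsv", run$run_id)))
    man <- rbind(man, data.frame(
      run_id = run$run_id, path = path,
      composition = run$metadata$composition %||% "unknown",
      cholesterol_fraction = run$metadata$cholesterol_fraction %||% NA))
  }
  tsv(man, "manifest.tsv")
  invisible(dir)
}

#' Read an ensemble from a manifest directory
#'
#' @param dir directory written by [write_ensemble()].
#' @param on_error `"stop"` or `"skip"` (skipped runs are reported in the
#'   attribute `failed`, with the error messages naming the files).
#' @return list with `topology`, `runs` and `manifest`.
#' @export
read_ensemble <- function(dir, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  beads <- rd("topology_beads.tsv")
  nb <- rd("nonbonded.tsv")
  hrt <- rd("helix_ranges.tsv")
  hr <- lapply(seq_len(nrow(hrt)), function(i) c(hrt$first[i], hrt$last[i]))
  names(hr) <- hrt$helix
  hr <- hr[order(vapply(hr, `[`, 0, 1))]
  topo <- topology(beads, hr,
                   data.frame(type_i = nb$type_i, type_j = nb$type_j,
                              C6 = nb$C6, C12 = nb$C12))
  man <- rd("manifest.tsv")
  runs <- list(); failed <- character(0)
  for (i in seq_len(nrow(man))) {
    res <- tryCatch(
      suppressWarnings(
        read_gro_trajectory(file.path(dir, man$path[i]), man$run_id[i],
                            list(composition = man$composition[i],
                                 cholesterol_fraction =
                                   man$cholesterol_fraction[i]))$run),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("run %s: %s", man$run_id[i], conditionMessage(res))
      if (on_error == "stop") stop(msg)
      failed <- c(failed, msg)
    } else {
      runs[[length(runs) + 1L]] <- res
    }
  }
  structure(list(topology = topo, runs = runs, manifest = man),
            failed = failed)
}

#' Synthesize an ensemble and write it to disk
#'
#' Thin wrapper over [simulate_ensemble()] + [write_ensemble()] with the
#' same determinism contract (identical config and seed give identical
#' output).
#'
#' @param config a `synthetic_config`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
synthesize_ensemble <- function(config, dir) {
  write_ensemble(simulate_ensemble(config), dir)
}

#' Pipeline configuration
#'
#' @param bind_threshold,unbind_threshold dimer criterion thresholds,
#'   kJ/mol.
#' @param orientation_window final orientation-sampling window, ns.
#' @param bandwidth KDE bandwidth, degrees.
#' @param grid_size KDE/watershed grid cells per axis.
#' @param min_height_fraction maxima noise floor.
#' @param equilibration_cut rate-fit equilibration cut, ns.
#' @param T temperature, K.
#' @param V double-layer volume, nm^3; NULL = box area times measured
#'   bilayer thickness.
#' @param contact_cutoff cholesterol contact cutoff, nm.
#' @param occupancy_window cholesterol occupancy window, ns.
#' @param diffusion_species species to report diffusion for.
#' @param fit_window MSD fit window, ns.
#' @param dimer_cut,analysis_span diffusion protocol: exclude runs that
#'   dimerized before `dimer_cut` ns and analyse the initial
#'   `analysis_span` ns (see [diffusion_report()]).
#' @param max_failure_fraction largest tolerated fraction of failed runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bind_threshold = -50, unbind_threshold = -1,
                            orientation_window = 50, bandwidth = 10,
                            grid_size = 360L, min_height_fraction = 0.05,
                            equilibration_cut = 500, T = 310, V = NULL,
                            contact_cutoff = 0.62,
                            occupancy_window = c(200, 1000),
                            diffusion_species = c("protein", "POPC"),
                            fit_window = c(5, 20),
                            dimer_cut = 250, analysis_span = 200,
                            max_failure_fraction = 0.1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on an ensemble
#'
#' Stages, in dependency order: interaction-energy timelines and the
#' bound/unbound classification; orientation sampling over the final
#' window of bound runs; periodic KDE + watershed segmentation and
#' configuration populations; binding kinetics and thermodynamics;
#' lateral diffusion; cholesterol contacts and bilayer thickness. Failing
#' runs are skipped and reported; the pipeline aborts if more than
#' `config$max_failure_fraction` of the runs fail.
#'
#' @param ensemble list with `topology` and `runs` (from
#'   [simulate_ensemble()] or [read_ensemble()]), or a directory path to
#'   read.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for tab-separated reports.
#' @return list with `timelines`, `orientation`, `field`, `labels`,
#'   `spreading`, `populations`, `kinetics`, `diffusion`, `thickness`,
#'   `occupancy`, `intercalation`, `failed_runs`.
#' @export
run_pipeline <- function(ensemble, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(ensemble)) ensemble <- read_ensemble(ensemble, "skip")
  topo <- ensemble$topology
  runs <- ensemble$runs
  failed <- attr(ensemble, "failed") %||% character(0)

  timelines <- list(); orient <- NULL; kept <- integer(0)
  for (i in seq_along(runs)) {
    res <- tryCatch({
      es <- energy_series(runs[[i]], topo)
      tl <- classify_states(es, config$bind_threshold,
                            config$unbind_threshold)
      rec <- dimer_angle_sample(runs[[i]], topo, tl,
                                config$orientation_window)
      list(tl = tl, rec = rec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("run %s: %s", runs[[i]]$run_id,
                                  conditionMessage(res)))
      next
    }
    kept <- c(kept, i)
    timelines[[length(timelines) + 1L]] <- res$tl
    if (!is.null(res$rec) && nrow(res$rec)) {
      res$rec$run_id <- runs[[i]]$run_id
      res$rec$composition <- runs[[i]]$metadata$composition %||% "unknown"
      orient <- rbind(orient, res$rec)
    }
  }
  if (length(failed) > config$max_failure_fraction *
        (length(runs) + length(failed)))
    stop("pipeline failed on too many runs:\n  ",
         paste(failed, collapse = "\n  "))
  runs <- runs[kept]

  field <- NULL; labels <- NULL; spreading <- NULL; populations <- NULL
  if (!is.null(orient) && nrow(orient)) {
    field <- periodic_kde(orient, config$bandwidth, config$grid_size)
    labels <- watershed(field, find_maxima(field,
                                           config$min_height_fraction))
    spreading <- label_spreading(field, labels)
    populations <- population_report(assign_frames(orient, labels),
                                     orient$composition)
  }

  thickness <- tryCatch(bilayer_thickness(runs[[1]], topo),
                        error = function(e) NA_real_)
  V <- config$V %||% double_layer_volume(runs[[1]]$box,
                                         if (is.na(thickness)) runs[[1]]$box[3]
                                         else thickness)
  kin <- kinetics_report(timelines, V, config$T, config$equilibration_cut)

  diffusion <- NULL
  for (sp in config$diffusion_species) {
    if (!any(topo$beads$species == sp)) next
    diffusion <- rbind(diffusion, tryCatch(
      diffusion_report(runs, topo, timelines, sp, config$fit_window,
                       config$dimer_cut, config$analysis_span),
      error = function(e) NULL))
  }

  occupancy <- NULL
  if (any(topo$beads$species == "CHOL")) {
    occupancy <- tryCatch(
      residue_occupancy(runs[[1]], topo, 1L, config$occupancy_window,
                        config$contact_cutoff),
      error = function(e) NULL)
  }
  intercal <- NULL
  if (any(topo$beads$species == "CHOL")) {
    bound_end <- vapply(seq_along(runs), function(i) {
      tl <- timelines[[i]]; tl$bound[length(tl$bound)]
    }, logical(1))
    if (any(bound_end)) {
      p <- vapply(which(bound_end), function(i)
        intercalation_report(runs[[i]], topo, config$orientation_window,
                             config$contact_cutoff)$p_at_least_one,
        numeric(1))
      intercal <- data.frame(run_id = vapply(runs[which(bound_end)],
                                             function(r)
                                               as.character(r$run_id), ""),
                             p_at_least_one = p)
    }
  }

  out <- list(timelines = timelines, orientation = orient, field = field,
              labels = labels, spreading = spreading,
              populations = populations, kinetics = kin,
              diffusion = diffusion, thickness = thickness,
              occupancy = occupancy, intercalation = intercal,
              failed_runs = failed)
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

# Tab-separated report bundle; numeric tables round-trip losslessly at
# full double precision (%.17g).
write_pipeline_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(results$orientation)) tsv(results$orientation,
                                         "orientation.tsv")
  if (!is.null(results$spreading)) tsv(results$spreading, "spreading.tsv")
  if (!is.null(results$populations)) tsv(results$populations,
                                         "populations.tsv")
  tsv(results$kinetics, "kinetics.tsv")
  if (!is.null(results$diffusion)) tsv(results$diffusion, "diffusion.tsv")
  if (!is.null(results$occupancy)) tsv(as.data.frame(results$occupancy),
                                       "occupancy.tsv")
  if (!is.null(results$intercalation)) tsv(results$intercalation,
                                           "intercalation.tsv")
  summary <- c(
    sprintf("runs_analyzed\t%d", length(results$timelines)),
    sprintf("runs_failed\t%d", length(results$failed_runs)),
    sprintf("bilayer_thickness_nm\t%.6g", results$thickness),
    sprintf("k_per_s\t%.10g", results$kinetics$k),
    sprintf("P0_over_P1\t%.10g", results$kinetics$P0_over_P1),
    sprintf("K_D\t%.10g", results$kinetics$K_D),
    sprintf("dG_kJ_per_mol\t%.10g", results$kinetics$dG))
  writeLines(summary, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
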