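# End-to-end orchestration: simulate -> extract -> stability ->
# redundancy -> report, with flat CSV intermediates so each stage is
# independently testable and resumable.

#' Run configuration
#'
#' @param design a [study_design()].
#' @param cfg a [radstab_config()].
#' @param dictionary a [feature_dictionary()].
#' @param thresholds correlation thresholds for the redundancy sweep.
#' @param methods correlation methods.
#' @param ccc_thresholds CCC thresholds for the stability summary.
#' @param write_volumes write each nodule volume and mask as NIfTI
#'   (`.nii.gz`) under `out/volumes` during the extract stage.
#' @param seed master seed; overrides `design$seed` when given.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = study_design(),
                       cfg = radstab_config(),
                       dictionary = default_dictionary(),
                       thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                       methods = c("pearson", "spearman"),
                       ccc_thresholds = c(0.75, 0.95),
                       write_volumes = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  structure(list(design = design, cfg = cfg, dictionary = dictionary,
                 thresholds = thresholds, methods = methods,
                 ccc_thresholds = ccc_thresholds,
                 write_volumes = write_volumes),
            class = "run_config")
}

# Deterministic hash of the configuration (md5 of its deparsed form).
#' @noRd
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[c("design", "thresholds", "methods",
                              "ccc_thresholds")]), tf)
  unname(tools::md5sum(tf))
}

# CSV with a provenance header comment; read back with read_radstab_csv.
#' @noRd
write_radstab_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# radstab seed=%d config=%s",
                     config$design$seed, config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a pipeline CSV (skipping the provenance header)
#' @param path CSV path written by [run_pipeline()].
#' @return data frame.
#' @export
read_radstab_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Run the full stability-and-redundancy pipeline
#'
#' Executes simulate, extract, stability, redundancy and report stages,
#' writing flat CSV/JSON intermediates under `out`:
#' `manifest.csv`, `features.csv`, `stability.csv`, `summary.json`,
#' `subgroups.csv`, `graph_T*.graphml`/`edges_T*.csv`, and `report.md`.
#' Stages whose outputs already exist are skipped (`resume = TRUE`), so
#' deleting e.g. only the stability outputs recomputes only stability and
#' report. All numeric outputs are deterministic functions of the
#' configuration and master seed; every CSV carries a header comment with
#' the seed and a configuration hash.
#'
#' @param config a [run_config()].
#' @param out output directory (created if missing).
#' @param resume skip stages whose outputs exist.
#' @param verbose print stage progress.
#' @return run manifest: list of stage output paths, invisibly classed as
#'   `radstab_run`.
#' @export
run_pipeline <- function(config = run_config(), out = "radstab_run",
                         resume = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list(
    manifest = file.path(out, "manifest.csv"),
    dictionary = file.path(out, "dictionary.json"),
    features = file.path(out, "features.csv"),
    stability = file.path(out, "stability.csv"),
    summary = file.path(out, "summary.json"),
    subgroups = file.path(out, "subgroups.csv"),
    report = file.path(out, "report.md"))
  design <- config$design

  # -- simulate: manifest of the cohort design --------------------------------
  if (!resume || !file.exists(paths$manifest)) {
    say("stage simulate: writing cohort manifest")
    grid <- expand.grid(init_id = seq_len(design$n_inits_per_algorithm),
                        algorithm_id = seq_len(design$n_algorithms),
                        nodule_id = seq_len(design$n_nodules))
    grid <- grid[, c("nodule_id", "algorithm_id", "init_id")]
    grid <- grid[order(grid$nodule_id, grid$algorithm_id, grid$init_id), ]
    grid$volume_path <- if (config$write_volumes)
      file.path("volumes", sprintf("nodule%03d.nii.gz", grid$nodule_id))
    else NA_character_
    grid$mask_path <- if (config$write_volumes)
      file.path("volumes", sprintf("nodule%03d_alg%d_init%d.nii.gz",
                                   grid$nodule_id, grid$algorithm_id,
                                   grid$init_id))
    else NA_character_
    write_radstab_csv(grid, paths$manifest, config)
    write_dictionary(config$dictionary, paths$dictionary)
  } else say("stage simulate: outputs exist, skipping")

  # -- extract: regenerate volumes deterministically and extract features -----
  if (!resume || !file.exists(paths$features)) {
    say("stage extract: %d nodules x %d segmentations",
        design$n_nodules, design$n_algorithms * design$n_inits_per_algorithm)
    if (config$write_volumes)
      dir.create(file.path(out, "volumes"), showWarnings = FALSE)
    nodules <- sample_nodules(design)
    rows <- list()
    for (i in seq_len(design$n_nodules)) {
      t0 <- proc.time()[["elapsed"]]
      sim <- simulate_nodule(design, i, nodules)
      if (config$write_volumes) {
        write_nifti_volume(sim$volume,
                           file.path(out, "volumes",
                                     sprintf("nodule%03d.nii.gz", i)))
        for (seg in sim$segmentations)
          write_nifti_mask(seg, file.path(
            out, "volumes", sprintf("nodule%03d_alg%d_init%d.nii.gz", i,
                                    seg$algorithm_id, seg$init_id)))
      }
      for (seg in sim$segmentations) {
        fv <- tryCatch(
          extract_all(sim$volume, seg, config$dictionary, config$cfg),
          error = function(e)
            stop(sprintf("extract stage failed at nodule %d, algorithm %d, init %d: %s",
                         i, seg$algorithm_id, seg$init_id,
                         conditionMessage(e)), call. = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          nodule_id = seg$nodule_id, algorithm_id = seg$algorithm_id,
          init_id = seg$init_id, as.list(as.numeric(fv)) |>
            stats::setNames(names(fv)), check.names = FALSE)
      }
      say("  nodule %d/%d done (%.1f s)", i, design$n_nodules,
          proc.time()[["elapsed"]] - t0)
    }
    tab <- feature_table(do.call(rbind, rows))
    write_radstab_csv(tab, paths$features, config)
  } else say("stage extract: outputs exist, skipping")

  # -- stability --------------------------------------------------------------
  if (!resume || !file.exists(paths$stability)) {
    say("stage stability: repeated-measures CCC per feature")
    tab <- feature_table(read_radstab_csv(paths$features))
    stab <- feature_stability(tab, config$dictionary)
    write_radstab_csv(as.data.frame(stab), paths$stability, config)
    summ <- stability_summary(stab, config$dictionary,
                              thresholds = config$ccc_thresholds)
    an <- tryCatch(class_anova(stab, config$dictionary),
                   error = function(e) NULL)
    jsonlite::write_json(
      list(seed = design$seed, config = config_hash(config),
           overall_fractions = as.list(summ$overall_fractions),
           per_class = summ$per_class,
           anova = if (!is.null(an)) an[c("F", "p_value")] else NULL),
      paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else say("stage stability: outputs exist, skipping")

  # -- redundancy -------------------------------------------------------------
  if (!resume || !file.exists(paths$subgroups)) {
    say("stage redundancy: |CC| graphs over %d thresholds",
        length(config$thresholds))
    tab <- feature_table(read_radstab_csv(paths$features))
    sweep <- subgroup_sweep(tab, config$thresholds, config$methods)
    write_radstab_csv(as.data.frame(sweep), paths$subgroups, config)
    mats <- attr(sweep, "matrices")
    if (!is.null(mats)) {
      for (T in config$thresholds) {
        g <- threshold_graph(mats[[config$methods[1]]], T)
        export_graph(g, config$dictionary,
                     file.path(out, sprintf("graph_T%g.graphml", T)),
                     edges_csv = file.path(out, sprintf("edges_T%g.csv", T)))
      }
    }
  } else say("stage redundancy: outputs exist, skipping")

  # -- report -----------------------------------------------------------------
  if (!resume || !file.exists(paths$report)) {
    say("stage report")
    render_report(out, config)
  } else say("stage report: outputs exist, skipping")

  invisible(structure(paths, class = "radstab_run"))
}

#' Write an image volume / segmentation mask as NIfTI
#'
#' @param volume an [image_volume()]; `seg` a [seg_record()].
#' @param path output `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @param seg a [seg_record()].
#' @export
write_nifti_mask <- function(seg, path) {
  img <- RNifti::asNifti(array(as.integer(seg$mask), dim(seg$mask)),
                         pixdim = seg$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume / mask pair
#'
#' @param volume_path,mask_path `.nii`/`.nii.gz` paths.
#' @return list with an [image_volume()] and a logical mask array.
#' @export
read_nifti_pair <- function(volume_path, mask_path) {
  v <- RNifti::readNifti(volume_path)
  m <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(v)[1:3]
  list(volume = image_volume(array(as.numeric(v), dim(v)[1:3]), sp),
       mask = array(as.numeric(m) > 0.5, dim(m)[1:3]))
}
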