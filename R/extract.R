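#' Full extraction configuration
#'
#' Bundles the preprocessing, texture and margin settings used by
#' [extract_all()].
#'
#' @param preprocess a [preprocess_config()].
#' @param texture a [texture_config()].
#' @param n_normals surface-normal sample count for margin features.
#' @param lsd_scale mm isotropic grid for local shape (roughness) features.
#' @param intensity_bin_width HU histogram bin width.
#' @return An object of class `radstab_config`.
#' @export
radstab_config <- function(preprocess = preprocess_config(),
                           texture = texture_config(),
                           n_normals = 800,
                           lsd_scale = 1,
                           intensity_bin_width = 25) {
  structure(list(preprocess = preprocess, texture = texture,
                 n_normals = n_normals, lsd_scale = lsd_scale,
                 intensity_bin_width = intensity_bin_width),
            class = "radstab_config")
}

#' Extract every dictionary feature for one segmentation record
#'
#' Runs [preprocess()] once, then each feature family required by the
#' dictionary. The result carries exactly the dictionary's feature names;
#' families that fail on a record produce `NA` values (with the error
#' recorded in the `"failures"` attribute) rather than aborting the
#' record. Per-family wall-clock timings are attached as the `"timings"`
#' attribute. The extraction is a pure function of (volume, mask, cfg):
#' repeated calls give identical vectors.
#'
#' @param volume an [image_volume()] on the segmentation's grid.
#' @param seg a [seg_record()] (or bare logical mask).
#' @param dictionary a [feature_dictionary()]; only its feature classes /
#'   subclasses determine which families run.
#' @param cfg a [radstab_config()].
#' @return named numeric vector over `dictionary$name`, with identifier
#'   attributes `nodule_id`, `algorithm_id`, `init_id` when `seg` is a
#'   [seg_record()].
#' @export
extract_all <- function(volume, seg, dictionary = default_dictionary(),
                        cfg = radstab_config()) {
  mask <- if (inherits(seg, "seg_record")) seg$mask else seg
  if (!identical(dim(volume$data), dim(mask)))
    stop("volume and mask grids differ", call. = FALSE)
  dictionary <- feature_dictionary(dictionary)
  pp <- preprocess(volume, mask, cfg$preprocess)
  iso_vol <- pp$volume; iso_mask <- pp$mask
  sp <- iso_vol$spacing

  values <- numeric(0)
  timings <- c()
  failures <- list()
  run_family <- function(label, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      failures[[label]] <<- conditionMessage(e)
      NULL
    })
    timings[[label]] <<- proc.time()[["elapsed"]] - t0
    if (!is.null(res)) values <<- c(values, res)
    invisible(NULL)
  }

  classes <- unique(dictionary$feature_class)
  subclasses <- unique(dictionary$subclass)
  if (any(classes %in% c("Size")))
    run_family("size", function() size_features(iso_mask, sp))
  if (any(classes %in% "GSD"))
    run_family("gsd", function() global_shape_features(iso_mask, sp))
  if (any(classes %in% "LSD"))
    run_family("lsd", function() {
      rs <- resample_for_texture(iso_vol, iso_mask, cfg$lsd_scale,
                                 margin_mm = 6)
      local_shape_features(rs$mask, rs$volume$spacing)
    })
  if (any(classes %in% "Intensity"))
    run_family("intensity", function()
      intensity_features(iso_vol, iso_mask, cfg$intensity_bin_width))
  if (any(classes %in% "Margin"))
    run_family("margin", function() {
      rs <- resample_for_texture(iso_vol, iso_mask, cfg$texture$rl_scale,
                                 margin_mm = 12)
      ring <- tryCatch(parenchyma_mask(rs$mask, rs$volume$spacing),
                       error = function(e) NULL)
      ring_stats <- if (!is.null(ring)) {
        rv <- rs$volume$data[ring]
        c(mean(rv), stats::sd(rv), hist_entropy(rv, bin_width = 25))
      } else c(NA_real_, NA_real_, NA_real_)
      mf <- margin_features(iso_vol, iso_mask, n_normals = cfg$n_normals,
                            ring = FALSE)
      mf[c("mar_parenchyma_mean_hu", "mar_parenchyma_sd_hu",
           "mar_parenchyma_entropy")] <- ring_stats
      mf
    })
  if ("GLCM" %in% subclasses) {
    run_family("glcm3d", function() glcm_features(iso_vol, iso_mask, cfg$texture))
    run_family("glcm2d", function() glcm_features_2d(iso_vol, iso_mask, cfg$texture))
  }
  if ("RunLength" %in% subclasses)
    run_family("runlength", function() runlength_features(iso_vol, iso_mask, cfg$texture))
  if ("Laws" %in% subclasses)
    run_family("laws", function() laws_features(iso_vol, iso_mask, cfg$texture))
  if ("LoG" %in% subclasses)
    run_family("log", function() log_features(iso_vol, iso_mask, cfg$texture))
  if ("Wavelet" %in% subclasses)
    run_family("wavelet", function() wavelet_features(iso_vol, iso_mask, cfg$texture))

  out <- rep(NA_real_, nrow(dictionary))
  names(out) <- dictionary$name
  common <- intersect(names(values), dictionary$name)
  out[common] <- values[common]
  if (inherits(seg, "seg_record")) {
    attr(out, "nodule_id") <- seg$nodule_id
    attr(out, "algorithm_id") <- seg$algorithm_id
    attr(out, "init_id") <- seg$init_id
  }
  attr(out, "timings") <- unlist(timings)
  attr(out, "failures") <- failures
  out
}

#' Feature table
#'
#' A data frame with identifier columns `nodule_id`, `algorithm_id`,
#' `init_id` followed by one numeric column per feature; one row per
#' segmentation record. Row keys must be unique and every nodule must
#' carry the same replicate design.
#'
#' @param df data frame with the identifier columns and feature columns.
#' @return An object of class `feature_table` (data frame subclass).
#' @export
feature_table <- function(df) {
  df <- as.data.frame(df)
  ids <- c("nodule_id", "algorithm_id", "init_id")
  miss <- setdiff(ids, names(df))
  if (length(miss))
    stop("feature table is missing identifier columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  key <- do.call(paste, df[ids])
  if (anyDuplicated(key))
    stop("duplicate (nodule_id, algorithm_id, init_id) rows", call. = FALSE)
  df <- df[order(df$nodule_id, df$algorithm_id, df$init_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @noRd
feature_names <- function(table) {
  setdiff(names(table), c("nodule_id", "algorithm_id", "init_id"))
}

#' Extract features for a whole cohort of segmentation records
#'
#' @param sims list of per-nodule simulations as from [simulate_nodule()],
#'   or a `simulate_cohort()` result plus volumes.
#' @param dictionary a [feature_dictionary()].
#' @param cfg a [radstab_config()].
#' @param verbose print per-nodule progress.
#' @return A [feature_table()].
#' @export
extract_cohort <- function(sims, dictionary = default_dictionary(),
                           cfg = radstab_config(), verbose = FALSE) {
  rows <- list()
  for (sim in sims) {
    for (seg in sim$segmentations) {
      fv <- extract_all(sim$volume, seg, dictionary, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        nodule_id = seg$nodule_id, algorithm_id = seg$algorithm_id,
        init_id = seg$init_id, as.list(fv), check.names = FALSE)
    }
    if (verbose)
      message(sprintf("extracted nodule %d (%d segmentations)",
                      sim$segmentations[[1]]$nodule_id,
                      length(sim$segmentations)))
  }
  feature_table(do.call(rbind, rows))
}
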