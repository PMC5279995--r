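# Feature dictionary: the machine-readable feature ontology. Six feature
# classes (Size, GSD, LSD, Intensity, Margin, Texture) and five texture
# subclasses (GLCM, LoG, Laws, RunLength, Wavelet); the subclass applies
# to Texture features only.

FEATURE_CLASSES <- c("Size", "GSD", "LSD", "Intensity", "Margin", "Texture")
TEXTURE_SUBCLASSES <- c("GLCM", "LoG", "Laws", "RunLength", "Wavelet")

#' Create a feature dictionary
#'
#' A dictionary is a data frame with one row per feature and columns
#' `name`, `feature_class`, `subclass`, `dimensionality`, `multiscale`,
#' `n_scales`, `description`, `pipeline_id`. Validation enforces the
#' closed-world ontology: exactly the six classes and five texture
#' subclasses are accepted, `subclass` must be `"none"` unless the class is
#' `Texture`, names must be unique, and `n_scales >= 1` iff `multiscale`.
#'
#' @param entries data frame with the columns above (missing metadata
#'   columns are filled with defaults).
#' @return A validated `feature_dictionary` (a data frame subclass).
#' @export
feature_dictionary <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  required <- c("name", "feature_class")
  miss <- setdiff(required, names(entries))
  if (length(miss))
    stop("dictionary is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(entries)
  if (is.null(entries$subclass)) entries$subclass <- rep("none", n)
  if (is.null(entries$dimensionality)) entries$dimensionality <- rep("3D", n)
  if (is.null(entries$multiscale)) entries$multiscale <- rep(FALSE, n)
  if (is.null(entries$n_scales))
    entries$n_scales <- ifelse(entries$multiscale, 1L, 0L)
  if (is.null(entries$description)) entries$description <- rep("", n)
  if (is.null(entries$pipeline_id)) entries$pipeline_id <- rep("radstab", n)
  entries$multiscale <- as.logical(entries$multiscale)
  entries$n_scales <- as.integer(entries$n_scales)
  rownames(entries) <- NULL
  validate_dictionary(entries)
  class(entries) <- c("feature_dictionary", "data.frame")
  entries
}

#' @noRd
validate_dictionary <- function(entries) {
  dup <- entries$name[duplicated(entries$name)]
  if (length(dup))
    stop("duplicate feature names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- !entries$feature_class %in% FEATURE_CLASSES
  if (any(bad))
    stop("unknown feature_class for entries: ",
         paste(entries$name[bad], collapse = ", "), call. = FALSE)
  bad <- !entries$subclass %in% c(TEXTURE_SUBCLASSES, "none")
  if (any(bad))
    stop("unknown subclass for entries: ",
         paste(entries$name[bad], collapse = ", "), call. = FALSE)
  mismatch <- (entries$feature_class == "Texture") != (entries$subclass != "none")
  if (any(mismatch))
    stop("subclass must be set exactly for Texture features; offending entries: ",
         paste(entries$name[mismatch], collapse = ", "), call. = FALSE)
  bad <- !entries$dimensionality %in% c("2D", "3D")
  if (any(bad))
    stop("dimensionality must be 2D or 3D; offending entries: ",
         paste(entries$name[bad], collapse = ", "), call. = FALSE)
  bad <- entries$multiscale & entries$n_scales < 1L
  if (any(bad))
    stop("multiscale entries need n_scales >= 1: ",
         paste(entries$name[bad], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read / write a feature dictionary (JSON or CSV)
#'
#' The canonical on-disk format is a JSON list of entry objects; CSV with
#' the same column names is accepted. `write_dictionary` followed by
#' `read_dictionary` is the identity on the entry table.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return `read_dictionary`: a validated [feature_dictionary()].
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  entries <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    stop("dictionary must be .json or .csv, got: ", path, call. = FALSE))
  feature_dictionary(entries)
}

#' @param entries a [feature_dictionary()] (or coercible data frame).
#' @rdname read_dictionary
#' @export
write_dictionary <- function(entries, path) {
  entries <- feature_dictionary(entries)
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(entries)
  switch(ext,
    json = jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE,
                                pretty = TRUE),
    csv = utils::write.csv(df, path, row.names = FALSE),
    stop("dictionary must be .json or .csv, got: ", path, call. = FALSE))
  invisible(path)
}

#' Feature counts by pipeline, class and texture subclass
#'
#' @param entries a [feature_dictionary()].
#' @return data frame with columns `pipeline_id`, `feature_class`,
#'   `subclass`, `n`; marginal totals sum to `nrow(entries)`.
#' @export
class_counts <- function(entries) {
  entries <- feature_dictionary(entries)
  if (nrow(entries) == 0L)
    return(data.frame(pipeline_id = character(), feature_class = character(),
                      subclass = character(), n = integer()))
  agg <- stats::aggregate(list(n = rep(1L, nrow(entries))),
                          by = list(pipeline_id = entries$pipeline_id,
                                    feature_class = entries$feature_class,
                                    subclass = entries$subclass),
                          FUN = sum)
  agg[order(agg$pipeline_id, agg$feature_class, agg$subclass), , drop = FALSE]
}

#' The package's reference feature dictionary
#'
#' Declares the full feature set computed by [extract_all()]: about 125
#' features covering every ontology class and every texture subclass, with
#' one reference implementation per family rather than any site's exact
#' feature list. GLCM features are multiscale (1, 2, 3 mm);
#' Laplacian-of-Gaussian features use three sigma values; the 2D entries
#' are computed on the maximal-diameter axial slice.
#'
#' @return A [feature_dictionary()].
#' @export
default_dictionary <- function() {
  e <- list()
  add <- function(name, cls, sub = "none", dim = "3D", multi = FALSE, ns = 0L,
                  desc = "") {
    data.frame(name = name, feature_class = cls, subclass = sub,
               dimensionality = dim, multiscale = multi, n_scales = ns,
               description = desc, pipeline_id = "radstab",
               stringsAsFactors = FALSE)
  }
  e$size <- add(c("size_volume_mm3", "size_surface_area_mm2",
                  "size_max_diameter_3d_mm", "size_bbox_x_mm", "size_bbox_y_mm",
                  "size_bbox_z_mm", "size_equiv_sphere_diameter_mm"),
                "Size", desc = "mask-based 3D size measure")
  e$size2d <- add(c("size_area_max_slice_mm2", "size_max_diameter_2d_mm"),
                  "Size", dim = "2D",
                  desc = "computed on the maximal-diameter axial slice")
  e$gsd <- add(c("gsd_sphericity", "gsd_compactness",
                 "gsd_eccentricity_major_minor", "gsd_elongation",
                 "gsd_radius_mean_mm", "gsd_radius_sd_mm", "gsd_radius_max_mm",
                 "gsd_radius_cv"),
               "GSD", desc = "global shape descriptor")
  e$lsd <- add(c("lsd_roughness_mean_mm", "lsd_roughness_sd_mm",
                 "lsd_roughness_max_mm"),
               "LSD",
               desc = "surface roughness vs a Gaussian-smoothed reference surface")
  e$int <- add(paste0("int_", c("mean", "median", "sd", "min", "max",
                                "skewness", "kurtosis", "energy", "entropy")),
               "Intensity", desc = "voxel intensity histogram statistic")
  e$mar <- add(c("mar_sigmoid_width_mean_mm", "mar_sigmoid_width_sd_mm",
                 "mar_sigmoid_height_mean_hu", "mar_sigmoid_height_sd_hu",
                 "mar_grad_boundary_mean", "mar_grad_boundary_sd",
                 "mar_grad_shell_in_mean", "mar_grad_shell_in_sd",
                 "mar_grad_shell_out_mean", "mar_grad_shell_out_sd",
                 "mar_parenchyma_mean_hu", "mar_parenchyma_sd_hu",
                 "mar_parenchyma_entropy"),
               "Margin",
               desc = "boundary sharpness / surrounding parenchyma measure")
  glcm_measures <- c("contrast", "dissimilarity", "homogeneity", "energy",
                     "entropy")
  g3 <- expand.grid(s = c(1, 2, 3), m = glcm_measures, a = c("mean", "range"),
                    stringsAsFactors = FALSE)
  e$glcm3 <- add(sprintf("tex_glcm3d_s%gmm_%s_%s", g3$s, g3$m, g3$a),
                 "Texture", sub = "GLCM", multi = TRUE, ns = 3L,
                 desc = "Haralick measure over 13 symmetric 3D offsets")
  e$glcm2 <- add(sprintf("tex_glcm2d_%s_mean", glcm_measures),
                 "Texture", sub = "GLCM", dim = "2D",
                 desc = "Haralick measure over 8 in-plane directions, max slice")
  e$rl <- add(sprintf("tex_rl_%s", c("sre", "lre", "gln", "rln", "rp",
                                     "lgre", "hgre")),
              "Texture", sub = "RunLength",
              desc = paste("run-length statistic averaged over 13 3D directions;",
                           "computed directly in the resampled mask region",
                           "(no rubber-band straightening transform)"))
  laws_triples <- c("E5L5L5", "S5L5L5", "R5L5L5", "W5L5L5", "E5E5E5")
  lw <- expand.grid(t = laws_triples, s = c("mean", "sd", "skewness", "kurtosis"),
                    stringsAsFactors = FALSE)
  e$laws <- add(sprintf("tex_laws_%s_%s", lw$t, lw$s),
                "Texture", sub = "Laws",
                desc = "rotation-invariant 3D Law's texture energy summary")
  lg <- expand.grid(s = c(0.5, 1.5, 2.5), m = c("mean", "sd"),
                    stringsAsFactors = FALSE)
  e$log <- add(sprintf("tex_log_s%gmm_%s", lg$s, lg$m),
               "Texture", sub = "LoG", multi = TRUE, ns = 3L,
               desc = "Laplacian-of-Gaussian response summary")
  bands <- as.vector(outer(outer(c("L", "H"), c("L", "H"), paste0),
                           c("L", "H"), paste0))
  wv <- expand.grid(b = tolower(bands), m = c("energy", "entropy"),
                    stringsAsFactors = FALSE)
  e$wav <- add(sprintf("tex_wav_%s_%s", wv$b, wv$m),
               "Texture", sub = "Wavelet",
               desc = "one-level 3D Haar sub-band summary")
  feature_dictionary(do.call(rbind, e))
}

#' Fixture dictionary mirroring the multi-site challenge submissions
#'
#' Builds a synthetic 830-entry dictionary whose per-site, per-class entry
#' counts transcribe the published submission table of the seven-institution
#' lung-nodule feature challenge (entry names are placeholders; only the
#' counts are meaningful). The printed column total for GLCM features in
#' that table (104) is inconsistent with its own rows, which sum to 105;
#' this fixture follows the rows, whose totals also reproduce the published
#' per-site totals (71, 10, 197, 15, 304, 49, 184) and grand total 830.
#'
#' @return A [feature_dictionary()] with 830 entries.
#' @export
consortium_dictionary <- function() {
  # per-site counts: Size, GSD, LSD, Intensity, Margin,
  #                  GLCM, LoG, Laws, RunLength, Wavelet
  counts <- rbind(
    CUMC     = c(3, 4, 8, 5,   0,  17, 6,  14,  0, 14),
    PM       = c(3, 2, 0, 5,   0,   0, 0,   0,  0,  0),
    Stanford = c(2, 1, 78, 17, 27, 72, 0,   0,  0,  0),
    UCLA     = c(1, 0, 0, 4,   0,  10, 0,   0,  0,  0),
    UIowa    = c(2, 6, 0, 9, 151,   0, 0, 136,  0,  0),
    UMICH    = c(4, 5, 0, 6,  18,   0, 0,   0, 16,  0),
    USF      = c(5, 0, 0, 0,   0,   6, 0, 125, 20, 28))
  cols <- data.frame(
    feature_class = c("Size", "GSD", "LSD", "Intensity", "Margin",
                      rep("Texture", 5)),
    subclass = c(rep("none", 5), "GLCM", "LoG", "Laws", "RunLength", "Wavelet"),
    stringsAsFactors = FALSE)
  rows <- list()
  for (site in rownames(counts)) {
    for (j in seq_len(ncol(counts))) {
      n <- counts[site, j]
      if (n == 0) next
      tag <- if (cols$subclass[j] == "none") cols$feature_class[j] else cols$subclass[j]
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s_%s_%03d", tolower(site), tolower(tag), seq_len(n)),
        feature_class = cols$feature_class[j],
        subclass = cols$subclass[j],
        dimensionality = "3D", multiscale = FALSE, n_scales = 0L,
        description = "synthetic placeholder entry (counts-only fixture)",
        pipeline_id = site, stringsAsFactors = FALSE)
    }
  }
  feature_dictionary(do.call(rbind, rows))
}
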