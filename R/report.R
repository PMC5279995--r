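#' Render the Markdown run report
#'
#' Regenerates `report.md` (plus PNG figures) from the stability and
#' redundancy outputs in a run directory: the CCC-by-class boxplot and
#' cumulative CCC curves, the overall fractions of features at or above
#' the CCC thresholds, the subgroup-count table, and component composition
#' summaries by feature class. Regenerating from the same run directory
#' yields identical report content.
#'
#' @param out run directory containing `stability.csv` and `subgroups.csv`.
#' @param config the [run_config()] of the run (for the dictionary and
#'   thresholds).
#' @return path of the report, invisibly.
#' @export
render_report <- function(out, config) {
  need <- file.path(out, c("stability.csv", "subgroups.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing report inputs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stab <- read_radstab_csv(file.path(out, "stability.csv"))
  class(stab) <- c("feature_stability", "data.frame")
  sweep <- read_radstab_csv(file.path(out, "subgroups.csv"))
  dict <- config$dictionary
  summ <- stability_summary(stab, dict, thresholds = config$ccc_thresholds)
  an <- tryCatch(class_anova(stab, dict), error = function(e) NULL)

  fig <- file.path(out, "stability_by_class.png")
  grDevices::png(fig, width = 1200, height = 600, res = 110)
  plot(stab, dictionary = dict)
  grDevices::dev.off()

  md <- c(
    "# Radiomic feature stability and redundancy report",
    "",
    sprintf("Seed %d; %d features; %d segmentation records per feature design.",
            config$design$seed, nrow(stab),
            config$design$n_nodules * config$design$n_algorithms *
              config$design$n_inits_per_algorithm),
    "",
    "## Stability to segmentation (repeated-measures CCC)",
    "",
    sprintf("- %.1f%% of features have overall CCC >= %g",
            summ$overall_fractions, config$ccc_thresholds),
    if (!is.null(an))
      sprintf("- one-way ANOVA of overall CCC by feature class: F = %.3f, p = %.3g",
              an$F, an$p_value),
    "",
    "![CCC by class](stability_by_class.png)",
    "",
    "### Per-class overall CCC",
    "",
    md_table(summ$per_class),
    "",
    "## Redundancy: non-correlated subgroups by threshold",
    "",
    md_table(stats::reshape(sweep, idvar = "threshold", timevar = "method",
                            direction = "wide")),
    "",
    "## Component composition by feature class",
    "")
  # composition of multi-feature components at the highest threshold,
  # from the first method's exported graph
  comp_md <- tryCatch({
    tab <- feature_table(read_radstab_csv(file.path(out, "features.csv")))
    M <- correlation_matrix(tab, config$methods[1])
    g <- threshold_graph(M, max(config$thresholds))
    cs <- connected_subgroups(g)
    cls <- dict$feature_class[match(names(cs$membership), dict$name)]
    big <- which(cs$sizes >= 2)
    if (length(big)) {
      comp_tab <- table(component = cs$membership[cs$membership %in% big],
                        class = cls[cs$membership %in% big])
      md_table(as.data.frame.matrix(comp_tab))
    } else "All components are singletons at the highest threshold."
  }, error = function(e) sprintf("(not available: %s)", conditionMessage(e)))
  md <- c(md, comp_md, "")
  writeLines(md, file.path(out, "report.md"))
  invisible(file.path(out, "report.md"))
}

# minimal data frame -> Markdown table
#' @noRd
md_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Read a YAML run configuration
#'
#' Builds a [run_config()] from a YAML file with optional top-level keys
#' `design`, `preprocess`, `texture`, `thresholds`, `methods`,
#' `ccc_thresholds`, `seed`, `write_volumes`, `dictionary` (path to a
#' dictionary JSON/CSV). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("design", "preprocess", "texture", "thresholds", "methods",
             "ccc_thresholds", "seed", "write_volumes", "dictionary")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  design <- do.call(study_design, if (is.null(y$design)) list() else y$design)
  pp <- do.call(preprocess_config,
                if (is.null(y$preprocess)) list() else y$preprocess)
  tex <- do.call(texture_config, if (is.null(y$texture)) list() else y$texture)
  dict <- if (is.null(y$dictionary)) default_dictionary()
          else read_dictionary(y$dictionary)
  args <- list(design = design,
               cfg = radstab_config(preprocess = pp, texture = tex),
               dictionary = dict)
  for (k in c("thresholds", "methods", "ccc_thresholds", "seed",
              "write_volumes"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}
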