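# Feature stability to segmentation: Lin's concordance correlation
# coefficient (CCC), stratified over replicate pairs into intra-algorithm,
# inter-algorithm and overall estimates.

#' Lin's concordance correlation coefficient of one replicate pair
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, as in Lin's original definition. The
#' coefficient combines precision (Pearson correlation) and accuracy
#' (mean/variance shift): `|CCC| <= |Pearson|`, with equality only when the
#' two measurements agree in mean and variance. Conventions for degenerate
#' input: both vectors constant and equal gives 1; both constant and
#' unequal gives 0 (no agreement information); one constant gives 0 via
#' the formula.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   are dropped; at least 3 complete pairs required).
#' @return CCC in `[-1, 1]`, or `NA` with fewer than 3 complete pairs.
#' @examples
#' pairwise_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
pairwise_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2); sy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx + sy + (mx - my)^2
  if (denom == 0) {
    # both constant: equal -> perfect concordance, unequal impossible here
    return(1)
  }
  if (sx == 0 && sy == 0) return(0)  # both constant, different means
  2 * sxy / denom
}

# replicate column pairs of a design with algorithm/init labels
#' @noRd
replicate_pairs <- function(alg, mode) {
  n <- length(alg)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- alg[pairs[, 1]] == alg[pairs[, 2]]
  keep <- switch(mode,
                 overall = rep(TRUE, nrow(pairs)),
                 intra = same,
                 inter = !same)
  pairs[keep, , drop = FALSE]
}

# wide nodules x replicates matrix for one feature
#' @noRd
feature_wide <- function(table, feature) {
  reps <- unique(table[, c("algorithm_id", "init_id")])
  reps <- reps[order(reps$algorithm_id, reps$init_id), , drop = FALSE]
  nods <- sort(unique(table$nodule_id))
  W <- matrix(NA_real_, length(nods), nrow(reps))
  for (j in seq_len(nrow(reps))) {
    sub <- table[table$algorithm_id == reps$algorithm_id[j] &
                 table$init_id == reps$init_id[j], c("nodule_id", feature)]
    W[match(sub$nodule_id, nods), j] <- sub[[feature]]
  }
  list(W = W, alg = reps$algorithm_id)
}

#' Repeated-measures CCC of a feature across segmentations
#'
#' Treats each (algorithm, initialization) replicate as a rater measuring
#' the feature over nodules, and estimates agreement as the mean of Lin's
#' pairwise CCC over the selected unordered replicate pairs:
#' `intra` uses same-algorithm pairs (9 in a 3x3 design), `inter`
#' cross-algorithm pairs (27), and `overall` all pairs (36) - so the
#' overall estimate is the pair-count-weighted combination of the intra
#' and inter strata. Rows with missing values are dropped pairwise;
#' pairs with fewer than 3 complete nodules are skipped.
#'
#' @param table a [feature_table()].
#' @param feature feature (column) name.
#' @param mode one of `"overall"`, `"inter"`, `"intra"`.
#' @return list with `ccc` (or `NA` and a `reason` when fewer than 3
#'   usable nodules / no usable pair) and `n_nodules_used` (minimum
#'   complete pairs across the used column pairs).
#' @export
repeated_measures_ccc <- function(table, feature,
                                  mode = c("overall", "inter", "intra")) {
  mode <- match.arg(mode)
  if (!feature %in% names(table))
    stop("unknown feature: ", feature, call. = FALSE)
  fw <- feature_wide(table, feature)
  pairs <- replicate_pairs(fw$alg, mode)
  if (nrow(pairs) == 0L)
    return(list(ccc = NA_real_, n_nodules_used = 0L,
                reason = "no replicate pairs for this mode"))
  cccs <- numeric(0); ns <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    x <- fw$W[, pairs[k, 1]]; y <- fw$W[, pairs[k, 2]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) next
    cccs <- c(cccs, pairwise_ccc(x[ok], y[ok]))
    ns <- c(ns, sum(ok))
  }
  if (!length(cccs))
    return(list(ccc = NA_real_, n_nodules_used = 0L,
                reason = "fewer than 3 usable nodules"))
  list(ccc = mean(cccs), n_nodules_used = min(ns))
}

#' Per-feature stability analysis of a feature table
#'
#' Computes the overall, inter- and intra-algorithm repeated-measures CCC
#' for every feature column.
#'
#' @param table a [feature_table()].
#' @param dictionary optional [feature_dictionary()] carried along for
#'   class-level summaries and plotting.
#' @return An object of class `feature_stability`: a data frame with
#'   columns `feature`, `ccc_overall`, `ccc_inter`, `ccc_intra`,
#'   `n_nodules_used`.
#' @export
feature_stability <- function(table, dictionary = NULL) {
  feats <- feature_names(table)
  rows <- lapply(feats, function(f) {
    ov <- repeated_measures_ccc(table, f, "overall")
    it <- repeated_measures_ccc(table, f, "inter")
    ia <- repeated_measures_ccc(table, f, "intra")
    data.frame(feature = f, ccc_overall = ov$ccc, ccc_inter = it$ccc,
               ccc_intra = ia$ccc, n_nodules_used = ov$n_nodules_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(dictionary)) {
    dictionary <- feature_dictionary(dictionary)
    attr(out, "dictionary") <- dictionary
  }
  class(out) <- c("feature_stability", "data.frame")
  out
}

#' @export
print.feature_stability <- function(x, ...) {
  cat(sprintf("Feature stability to segmentation: %d features\n", nrow(x)))
  ok <- is.finite(x$ccc_overall)
  if (any(ok)) {
    cat(sprintf("  overall CCC: median %.3f; %.0f%% >= 0.75, %.0f%% >= 0.95\n",
                stats::median(x$ccc_overall[ok]),
                100 * mean(x$ccc_overall[ok] >= 0.75),
                100 * mean(x$ccc_overall[ok] >= 0.95)))
    cat(sprintf("  mean intra CCC %.3f vs mean inter CCC %.3f\n",
                mean(x$ccc_intra[is.finite(x$ccc_intra)]),
                mean(x$ccc_inter[is.finite(x$ccc_inter)])))
  }
  invisible(x)
}

# attach dictionary classes to a stability result
#' @noRd
stability_classes <- function(results, dictionary) {
  dictionary <- feature_dictionary(dictionary)
  m <- match(results$feature, dictionary$name)
  if (anyNA(m))
    stop("features without dictionary entry: ",
         paste(results$feature[is.na(m)], collapse = ", "), call. = FALSE)
  dictionary$feature_class[m]
}

#' Class-level summary of feature stability
#'
#' Per feature class: five-number summary of the CCC distribution (the
#' boxplot data) and the fraction of features with CCC at or above each
#' threshold (the cumulative-histogram values), plus the same fractions
#' over all features.
#'
#' @param results a [feature_stability()].
#' @param dictionary a [feature_dictionary()] covering every feature.
#' @param thresholds CCC thresholds (default 0.75 and 0.95).
#' @param mode which CCC column to summarize.
#' @return list with `per_class` (data frame), `overall_fractions` (named
#'   vector, percent), and `n_missing` (features without finite CCC).
#' @export
stability_summary <- function(results, dictionary,
                              thresholds = c(0.75, 0.95),
                              mode = c("overall", "inter", "intra")) {
  mode <- match.arg(mode)
  col <- paste0("ccc_", mode)
  cls <- stability_classes(results, dictionary)
  v <- results[[col]]
  ok <- is.finite(v)
  per_class <- lapply(split(v[ok], cls[ok]), function(x) {
    qs <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    fr <- vapply(thresholds, function(t) 100 * mean(x >= t), numeric(1))
    c(n = length(x), min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
      max = qs[5], stats::setNames(fr, sprintf("pct_ge_%g", thresholds)))
  })
  per_class <- data.frame(feature_class = names(per_class),
                          do.call(rbind, per_class),
                          row.names = NULL, check.names = FALSE)
  overall <- vapply(thresholds, function(t) 100 * mean(v[ok] >= t), numeric(1))
  names(overall) <- sprintf("pct_ge_%g", thresholds)
  list(per_class = per_class, overall_fractions = overall,
       n_missing = sum(!ok), mode = mode)
}

#' One-way ANOVA of CCC by feature class
#'
#' Fixed-effects one-way analysis of variance testing whether the mean
#' CCC differs across feature classes.
#'
#' @inheritParams stability_summary
#' @return list with `F`, `p_value`, `df`.
#' @export
class_anova <- function(results, dictionary,
                        mode = c("overall", "inter", "intra")) {
  mode <- match.arg(mode)
  col <- paste0("ccc_", mode)
  cls <- stability_classes(results, dictionary)
  v <- results[[col]]
  ok <- is.finite(v)
  df <- data.frame(ccc = v[ok], cls = factor(cls[ok]))
  tab <- table(df$cls)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 classes with at least 2 features each", call. = FALSE)
  df <- df[df$cls %in% names(tab)[tab >= 1], , drop = FALSE]
  a <- stats::anova(stats::lm(ccc ~ cls, data = df))
  list(F = a$`F value`[1], p_value = a$`Pr(>F)`[1],
       df = c(a$Df[1], a$Df[2]))
}

#' Plot feature stability by class
#'
#' Draws the CCC-by-class boxplot and the per-class cumulative fraction of
#' features at or above each CCC value.
#'
#' @param x a [feature_stability()] with a dictionary attached (or pass
#'   `dictionary`).
#' @param dictionary a [feature_dictionary()].
#' @param mode which CCC column to plot.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the per-class CCC split.
#' @export
plot.feature_stability <- function(x, dictionary = attr(x, "dictionary"),
                                   mode = "overall", ...) {
  if (is.null(dictionary))
    stop("a feature dictionary is required for class-level plots", call. = FALSE)
  col <- paste0("ccc_", mode)
  cls <- stability_classes(x, dictionary)
  v <- x[[col]]
  ok <- is.finite(v)
  if (!any(ok)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no finite CCC values to plot")
    return(invisible(list()))
  }
  sp <- split(v[ok], cls[ok])
  sp <- sp[lengths(sp) > 0]
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::boxplot(sp, las = 2, ylab = sprintf("%s CCC", mode),
                    main = "CCC by feature class", ...)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = sprintf("%s CCC", mode),
                 ylab = "fraction of features >= CCC",
                 main = "Cumulative CCC by class")
  cols <- grDevices::hcl.colors(length(sp), "Dark 3")
  grid_t <- seq(0, 1, by = 0.01)
  for (i in seq_along(sp)) {
    frac <- vapply(grid_t, function(t) mean(sp[[i]] >= t), numeric(1))
    graphics::lines(grid_t, frac, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomleft", names(sp), col = cols, lwd = 2, cex = 0.8,
                   bty = "n")
  invisible(sp)
}

#' Simulate a feature table from a variance-components model
#'
#' Generates `value = nodule effect + algorithm offset + init noise` for a
#' single synthetic feature over a replicate design: nodule effects are
#' `N(0, sd_nodule^2)`, each algorithm contributes a fixed offset drawn
#' from `N(0, sd_algorithm^2)` (shared by its initializations), and each
#' replicate adds independent `N(0, sd_init^2)` noise. Useful for checking
#' the stability estimator: intra-algorithm CCC exceeds inter-algorithm
#' CCC whenever `sd_algorithm > 0`, and increasing `sd_init` lowers the
#' intra CCC.
#'
#' @param n_nodules,n_algorithms,n_inits design dimensions.
#' @param sd_nodule,sd_algorithm,sd_init standard deviations of the model
#'   components.
#' @param seed integer seed.
#' @param feature_name column name of the simulated feature.
#' @return A [feature_table()] with one feature column.
#' @export
simulate_feature_table <- function(n_nodules = 52, n_algorithms = 3,
                                   n_inits = 3, sd_nodule = 1,
                                   sd_algorithm = 0.3, sd_init = 0.1,
                                   seed = 1, feature_name = "feature") {
  set.seed(seed)
  nod <- stats::rnorm(n_nodules, sd = sd_nodule)
  alg <- stats::rnorm(n_algorithms, sd = sd_algorithm)
  grid <- expand.grid(init_id = seq_len(n_inits),
                      algorithm_id = seq_len(n_algorithms),
                      nodule_id = seq_len(n_nodules))
  grid$value <- nod[grid$nodule_id] + alg[grid$algorithm_id] +
    stats::rnorm(nrow(grid), sd = sd_init)
  names(grid)[names(grid) == "value"] <- feature_name
  feature_table(grid[, c("nodule_id", "algorithm_id", "init_id", feature_name)])
}
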