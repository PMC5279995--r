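# Feature redundancy: pairwise |correlation| matrices, thresholded
# undirected feature graphs, and connected-subgroup counts across a
# threshold sweep. Each feature is a node; the edge weight between two
# nodes is the absolute value of their Pearson or Spearman correlation
# over segmentation records, and edges with weights below a threshold T
# are removed. The number of resulting connected subgraphs (singletons
# included) measures the effective dimensionality of the feature set.

#' Absolute pairwise correlation matrix of a feature table
#'
#' `|Pearson|` or `|Spearman|` correlations between all feature columns,
#' pairwise-complete over rows. Constant columns (zero variance) have
#' undefined correlations: their off-diagonal entries are `NA` and the
#' column names are reported in the `"constant_features"` attribute.
#'
#' @param table a [feature_table()] (or plain numeric data frame /matrix
#'   of feature columns).
#' @param method `"pearson"` (the linear association) or `"spearman"`
#'   (rank-based, capturing monotone nonlinear association).
#' @return symmetric matrix of class `correlation_matrix` with values in
#'   `[0, 1]`, unit diagonal where defined, and a `"method"` attribute.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (is.data.frame(table)) {
    as.matrix(table[, setdiff(names(table),
                              c("nodule_id", "algorithm_id", "init_id")),
                    drop = FALSE])
  } else as.matrix(table)
  if (ncol(X) < 2L) stop("need at least 2 features", call. = FALSE)
  M <- abs(suppressWarnings(
    stats::cor(X, use = "pairwise.complete.obs", method = method)))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  const <- colnames(X)[!is.na(sds) & sds == 0]
  diag(M) <- ifelse(colnames(X) %in% const, NA_real_, 1)
  attr(M, "method") <- method
  attr(M, "constant_features") <- const
  class(M) <- c("correlation_matrix", "matrix")
  M
}

#' Threshold a correlation matrix into a feature graph
#'
#' Builds the undirected feature graph whose edge (i, j) is present iff
#' `|CC|(i, j)` is defined and at or above `T` (edges with weights below
#' the threshold are removed). All nodes are retained, so subgroups of a
#' single node are possible; undefined correlations (constant features)
#' contribute no edges.
#'
#' @param matrix a [correlation_matrix()].
#' @param T threshold in `[0, 1]`.
#' @return an [igraph::graph] with vertex attribute `name` and edge
#'   attribute `weight` (the |CC| values), and graph attribute `threshold`.
#' @export
threshold_graph <- function(matrix, T) {
  stopifnot(T >= 0, T <= 1)
  M <- unclass(matrix)
  A <- !is.na(M) & M >= T
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ends)) igraph::E(g)$weight <- M[ends]
  g <- igraph::set_graph_attr(g, "threshold", T)
  g
}

#' Connected subgroups of a feature graph
#'
#' Standard connected components; the count includes singleton nodes and
#' the partition is exhaustive and disjoint.
#'
#' @param graph an [igraph::graph] as from [threshold_graph()].
#' @return list with `membership` (named integer vector), `sizes`, and
#'   `count`.
#' @export
connected_subgroups <- function(graph) {
  comp <- igraph::components(graph)
  memb <- stats::setNames(as.integer(comp$membership),
                          names(comp$membership))
  list(membership = memb, sizes = as.integer(comp$csize),
       count = as.integer(comp$no))
}

#' Subgroup counts over a threshold sweep
#'
#' For each correlation method and each threshold, the number of connected
#' subgroups of the thresholded feature graph. Counts are non-decreasing
#' in the threshold for each method.
#'
#' @param table a [feature_table()].
#' @param thresholds thresholds in `[0, 1]` (default the conventional
#'   0.75, 0.80, 0.85, 0.90, 0.95 grid).
#' @param methods correlation methods to sweep.
#' @return An object of class `redundancy`: a data frame with columns
#'   `method`, `threshold`, `n_subgroups`, with the correlation matrices
#'   attached as the `"matrices"` attribute.
#' @export
subgroup_sweep <- function(table,
                           thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                           methods = c("pearson", "spearman")) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  feats <- if (is.data.frame(table))
    setdiff(names(table), c("nodule_id", "algorithm_id", "init_id"))
  else colnames(table)
  if (length(feats) == 1L) {
    out <- expand.grid(method = methods, threshold = thresholds,
                       stringsAsFactors = FALSE)
    out$n_subgroups <- 1L
    class(out) <- c("redundancy", "data.frame")
    return(out)
  }
  mats <- lapply(methods, function(m) correlation_matrix(table, m))
  names(mats) <- methods
  rows <- list()
  for (m in methods) {
    for (T in thresholds) {
      g <- threshold_graph(mats[[m]], T)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, threshold = T,
        n_subgroups = connected_subgroups(g)$count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "matrices") <- mats
  class(out) <- c("redundancy", "data.frame")
  out
}

#' @export
print.redundancy <- function(x, ...) {
  cat("Non-correlated feature subgroups by threshold\n")
  w <- stats::reshape(as.data.frame(x), idvar = "threshold",
                      timevar = "method", direction = "wide")
  names(w) <- sub("n_subgroups.", "", names(w), fixed = TRUE)
  print(w, row.names = FALSE)
  invisible(x)
}

#' Export a feature graph with dictionary attributes
#'
#' Writes GraphML (and optionally an edge-list CSV) with node attributes
#' `feature_class`, `subclass`, `pipeline_id` and `component_id`.
#' Singleton components can be dropped for display parity with typical
#' graph figures ("only groups with more than one node").
#'
#' @param graph an [igraph::graph] from [threshold_graph()].
#' @param dictionary a [feature_dictionary()] covering every node.
#' @param path output `.graphml` path.
#' @param edges_csv optional edge-list CSV path.
#' @param drop_singletons drop components of size 1 before export.
#' @return the exported graph, invisibly.
#' @export
export_graph <- function(graph, dictionary, path, edges_csv = NULL,
                         drop_singletons = FALSE) {
  dictionary <- feature_dictionary(dictionary)
  nodes <- igraph::V(graph)$name
  m <- match(nodes, dictionary$name)
  if (anyNA(m))
    stop("nodes without dictionary entry: ",
         paste(nodes[is.na(m)], collapse = ", "), call. = FALSE)
  comp <- igraph::components(graph)
  graph <- igraph::set_vertex_attr(graph, "feature_class",
                                   value = dictionary$feature_class[m])
  graph <- igraph::set_vertex_attr(graph, "subclass",
                                   value = dictionary$subclass[m])
  graph <- igraph::set_vertex_attr(graph, "pipeline_id",
                                   value = dictionary$pipeline_id[m])
  graph <- igraph::set_vertex_attr(graph, "component_id",
                                   value = as.integer(comp$membership))
  if (drop_singletons) {
    keep <- comp$csize[comp$membership] >= 2
    graph <- igraph::induced_subgraph(graph, which(keep))
  }
  igraph::write_graph(graph, path, format = "graphml")
  if (!is.null(edges_csv)) {
    el <- igraph::as_edgelist(graph)
    w <- if ("weight" %in% igraph::edge_attr_names(graph))
      igraph::E(graph)$weight else rep(NA_real_, nrow(el))
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2], weight = w),
                     edges_csv, row.names = FALSE)
  }
  invisible(graph)
}
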