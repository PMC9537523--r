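# Unsupervised phenotype clustering of neurons on the feature matrix:
# log-transform of skewed features, z-scaling, correlation distance that
# drops the adaptation index pairwise when it is undefined, and
# average-linkage agglomeration cut into k clusters.

#' Default feature columns used for clustering
#'
#' The cell feature vector minus redundant derived fields: the rheobase
#' latency is excluded in favor of the interpolated latency at rheobase +
#' 5 pA, and the resting potential is excluded because it is frequently
#' missing (I = 0 metadata). Only the adaptation index may be missing in
#' the resulting matrix.
#'
#' @return Character vector of feature names.
#' @export
default_cluster_features <- function() {
  c("rheobase", "latency_rheo_plus5", "adaptation_index", "fi_slope",
    "max_rate", "input_resistance", "tau", "capacitance", "sag_ratio",
    "threshold_v", "amplitude", "width", "ahp", "upstroke")
}

#' Default log-transformed feature columns
#'
#' Spike width, first-spike latency, input resistance, and capacitance have
#' right-skewed distributions and are log-transformed before scaling.
#'
#' @return Character vector of feature names.
#' @export
default_log_features <- function() {
  c("width", "latency_rheo_plus5", "input_resistance", "capacitance")
}

#' Build the cells-by-features matrix from a feature table
#'
#' Rows with missing values in any feature other than the adaptation index
#' are rejected (typically non-firing cells, which should be excluded
#' before clustering, mirroring the practice of clustering firing cells
#' only).
#'
#' @param ft Feature table ([extract_feature_table()] or
#'   [read_feature_table()]).
#' @param features Feature columns to use.
#' @return Numeric matrix with cell ids as row names.
#' @export
feature_matrix <- function(ft, features = default_cluster_features()) {
  stopifnot(is.data.frame(ft), "cell_id" %in% names(ft))
  missing_cols <- setdiff(features, names(ft))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(ft[, features, drop = FALSE])
  rownames(m) <- ft$cell_id
  hard <- setdiff(features, "adaptation_index")
  bad <- rownames(m)[!stats::complete.cases(m[, hard, drop = FALSE])]
  if (length(bad)) {
    stop("cells with missing non-adaptation features (drop them first): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (nrow(m) < 2L) stop("need at least two cells")
  m
}

#' Log-transform skewed features and scale all columns
#'
#' The listed columns are log-transformed, then every column is centered to
#' zero mean and scaled to unit variance (sample SD). Columns with zero
#' variance are dropped with a warning rather than erroring, which keeps
#' small cohorts usable.
#'
#' @param fm Numeric matrix from [feature_matrix()].
#' @param log_features Columns to log-transform; they must be strictly
#'   positive wherever present.
#' @return Scaled matrix (possibly with fewer columns).
#' @export
transform_features <- function(fm, log_features = default_log_features()) {
  stopifnot(is.matrix(fm))
  log_features <- intersect(log_features, colnames(fm))
  for (col in log_features) {
    x <- fm[, col]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive value in log column '", col, "' for cell ",
           rownames(fm)[bad[1]])
    }
    fm[, col] <- log(x)
  }
  mu <- colMeans(fm, na.rm = TRUE)
  sdev <- apply(fm, 2, stats::sd, na.rm = TRUE)
  zero_var <- !is.na(sdev) & sdev < 1e-12
  if (any(zero_var)) {
    warning("dropping zero-variance feature column(s): ",
            paste(colnames(fm)[zero_var], collapse = ", "))
    fm <- fm[, !zero_var, drop = FALSE]
    mu <- mu[!zero_var]
    sdev <- sdev[!zero_var]
  }
  scaled <- base::sweep(base::sweep(fm, 2, mu, "-"), 2, sdev, "/")
  scaled
}

#' Missing-aware correlation distance between cells
#'
#' `d(i, j) = 1 - cor(row_i, row_j)` (Pearson, over features). For any pair
#' in which either cell has an undefined adaptation index, the correlation
#' is computed over all features except the adaptation index, so a missing
#' adaptation never contaminates a distance.
#'
#' @param fm Scaled matrix from [transform_features()]; `adaptation_index`
#'   is the only column allowed to contain `NA`.
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   `[0, 2]`.
#' @export
correlation_distance <- function(fm) {
  stopifnot(is.matrix(fm))
  na_cols <- colnames(fm)[apply(fm, 2, anyNA)]
  if (length(setdiff(na_cols, "adaptation_index"))) {
    stop("only adaptation_index may contain missing values; found NA in: ",
         paste(setdiff(na_cols, "adaptation_index"), collapse = ", "))
  }
  n <- nrow(fm)
  has_adapt <- "adaptation_index" %in% colnames(fm)
  reduced <- if (has_adapt) {
    fm[, setdiff(colnames(fm), "adaptation_index"), drop = FALSE]
  } else fm
  if (ncol(reduced) < 3L) stop("need at least three shared features")
  adapt_ok <- if (has_adapt) !is.na(fm[, "adaptation_index"]) else
    rep(FALSE, n)
  # correlations across rows: full matrix for complete pairs, reduced for
  # pairs touching a missing adaptation index
  cor_full <- stats::cor(t(fm))
  cor_red <- stats::cor(t(reduced))
  use_red <- outer(!adapt_ok, !adapt_ok, "|")
  cmat <- ifelse(use_red, cor_red, cor_full)
  d <- 1 - cmat
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(fm), rownames(fm))
  d
}

#' Average-linkage clustering of the distance matrix
#'
#' Agglomerative clustering (UPGMA) on the correlation distance; the tree
#' is cut into `k` groups (`k = 5` reproduces the downstream phenotype
#' analysis).
#'
#' @param dm Distance matrix from [correlation_distance()].
#' @param k Number of clusters (1..n).
#' @return List with `dendrogram` (an `hclust` object) and `assignment`
#'   (named integer vector of cluster labels in 1..k).
#' @export
cluster_cells <- function(dm, k = 5) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (max(abs(dm - t(dm))) > 1e-10 || any(abs(diag(dm)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(dm)
  stopifnot(k >= 1, k <= n)
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  labels <- stats::cutree(hc, k = k)
  list(dendrogram = hc, assignment = labels)
}

#' Run the full clustering pipeline on a feature table
#'
#' Convenience wrapper: [feature_matrix()] (with cells missing hard
#' features dropped beforehand by the caller), [transform_features()],
#' [correlation_distance()], [cluster_cells()].
#'
#' @param ft Feature table.
#' @param k Number of clusters.
#' @param features,log_features See [feature_matrix()] and
#'   [transform_features()].
#' @return As [cluster_cells()], plus `distance` and `scaled` matrices.
#' @export
cluster_feature_table <- function(ft, k = 5,
                                  features = default_cluster_features(),
                                  log_features = default_log_features()) {
  fm <- feature_matrix(ft, features)
  scaled <- transform_features(fm, log_features)
  dm <- correlation_distance(scaled)
  cl <- cluster_cells(dm, k)
  c(cl, list(distance = dm, scaled = scaled))
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights of the average-linkage
#' tree.
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
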