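#' Differential correlation structure between two groups
#'
#' For each group, an adjacency matrix `A` is built from the absolute
#' Spearman correlations of the analytes (`a_ij = |rho_ij|`, diagonal 1).
#' The change matrix `C = |A1 - A2|` quantifies how strongly each analyte
#' pair is rewired between the groups, and the dissimilarity
#' `D = 1 - C / max(C)` (diagonal 0) makes strongly co-rewired pairs close,
#' ready for hierarchical clustering. The opposite reading of the
#' "difference matrix" — rewired pairs far apart, `D = C` — is available
#' via `direction = "change_as_distance"`.
#'
#' @param table A [sample_table()].
#' @param group_a,group_b Group labels with >= 4 samples each.
#' @param direction `"co_rewired_close"` (default) or
#'   `"change_as_distance"`.
#' @return List of class `adjacency_change` with `analytes`, `A1`, `A2`,
#'   `C`, `D`, `excluded` (zero-variance analytes), and `no_rewiring`
#'   (`TRUE` when `C` is identically zero, in which case `D` is `NULL`).
#' @export
adjacency_change <- function(table, group_a, group_b,
                             direction = c("co_rewired_close",
                                           "change_as_distance")) {
  stopifnot(inherits(table, "sample_table"))
  direction <- match.arg(direction)
  for (g in c(group_a, group_b)) {
    if (sum(table$meta$group == g) < 4) {
      stop("group needs >= 4 samples for rank correlation: ", g)
    }
  }
  A <- table$X[table$meta$group == group_a, , drop = FALSE]
  B <- table$X[table$meta$group == group_b, , drop = FALSE]
  va <- apply(A, 2, stats::var)
  vb <- apply(B, 2, stats::var)
  excluded <- colnames(A)[va == 0 | vb == 0]
  keep <- setdiff(colnames(A), excluded)
  if (length(keep) < 2) stop("fewer than 2 analytes with variance in both groups")
  adj <- function(M) {
    R <- abs(stats::cor(M[, keep, drop = FALSE], method = "spearman"))
    diag(R) <- 1
    R
  }
  A1 <- adj(A)
  A2 <- adj(B)
  C <- abs(A1 - A2)
  diag(C) <- 0
  no_rewiring <- max(C) == 0
  D <- NULL
  if (!no_rewiring) {
    D <- if (direction == "co_rewired_close") 1 - C / max(C) else C
    diag(D) <- 0
  }
  structure(list(analytes = keep, A1 = A1, A2 = A2, C = C, D = D,
                 excluded = excluded, no_rewiring = no_rewiring,
                 direction = direction),
            class = "adjacency_change")
}

#' Ward clustering of the rewiring structure with silhouette-selected k
#'
#' Agglomerative clustering (Ward linkage, `ward.D2` convention, on the
#' precomputed dissimilarity) of the analytes of an [adjacency_change()];
#' the dendrogram is cut at every `k` in `k_range` and the cut maximizing
#' the mean silhouette width (computed against the same dissimilarity) is
#' returned.
#'
#' @param change An [adjacency_change()] with `D` available.
#' @param k_range Integer vector of cluster counts to scan, within
#'   `[2, n_analytes - 1]`. Default `2:min(10, n - 1)`.
#' @return List of class `cluster_assignment`: `k`, `labels` (named per
#'   analyte), `mean_silhouette`, `silhouette_trace` (per scanned k),
#'   `hclust`.
#' @export
ward_silhouette <- function(change, k_range = NULL) {
  stopifnot(inherits(change, "adjacency_change"))
  if (change$no_rewiring || is.null(change$D)) {
    stop("no rewiring between groups: dissimilarity undefined")
  }
  n <- length(change$analytes)
  if (n < 4) stop("need >= 4 analytes to cluster")
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n_analytes - 1]")
  }
  hc <- stats::hclust(stats::as.dist(change$D), method = "ward.D2")
  trace <- vapply(k_range, function(k) {
    labels <- stats::cutree(hc, k = k)
    mean_silhouette(labels, change$D)
  }, 0)
  best <- which.max(trace)
  k <- k_range[best]
  labels <- stats::cutree(hc, k = k)
  names(labels) <- change$analytes
  structure(list(k = k, labels = labels, mean_silhouette = trace[best],
                 silhouette_trace = stats::setNames(trace, k_range),
                 hclust = hc),
            class = "cluster_assignment")
}

# mean silhouette width of a hard partition against a dissimilarity matrix
mean_silhouette <- function(labels, D) {
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}
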