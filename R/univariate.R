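#' Mann-Whitney two-sample test
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when `min(n, m) <= 8` and there are no ties; otherwise the tie-corrected
#' normal approximation (no continuity correction, which keeps the
#' rejection rate at the nominal level for the cohort sizes this pipeline
#' targets). `U` is the count-based statistic for `x` (number of (x, y)
#' pairs with x > y, ties counted 1/2).
#'
#' @param x,y Numeric vectors, each with at least one observation.
#' @return List with elements `U` and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = FALSE))
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, in input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise group comparison across the panel
#'
#' Runs [mann_whitney()] for every panel analyte between two groups and
#' adjusts the p-values across the panel with [bh_adjust()]. Direction is
#' the sign of the median difference of `group_b` relative to `group_a`.
#' Both the raw-p and FDR-adjusted significance flags are reported: marker
#' shortlists ("significant in at least one comparison") conventionally use
#' raw p < alpha, while the FDR-surviving subset is the stricter claim.
#'
#' @param table A [sample_table()].
#' @param group_a,group_b Group labels present in the table (>= 2 samples
#'   each).
#' @param alpha Significance level for the adjusted q (default 0.05).
#' @return A data frame of class `group_comparison` with one row per
#'   analyte: `analyte`, `comparison`, `U`, `p`, `q`, `direction`,
#'   `significant_raw` (p < alpha), `significant` (q < alpha).
#' @export
compare_groups <- function(table, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(table, "sample_table"))
  for (g in c(group_a, group_b)) {
    if (sum(table$meta$group == g) < 2) {
      stop("group absent or has fewer than 2 samples: ", g)
    }
  }
  A <- table$X[table$meta$group == group_a, , drop = FALSE]
  B <- table$X[table$meta$group == group_b, , drop = FALSE]
  res <- lapply(colnames(table$X), function(code) {
    mw <- mann_whitney(A[, code], B[, code])
    dm <- stats::median(B[, code]) - stats::median(A[, code])
    data.frame(analyte = code, U = mw$U, p = mw$p,
               direction = if (dm > 0) "up" else if (dm < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$comparison <- paste(group_a, "vs", group_b)
  out$significant_raw <- out$p < alpha
  out$significant <- out$q < alpha
  out <- out[, c("analyte", "comparison", "U", "p", "q", "direction",
                 "significant_raw", "significant")]
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Spearman association with time post-insult
#'
#' Correlates each analyte's concentration with the sampling time
#' (`time_h`), using average ranks for ties; p-values are two-sided from
#' the t approximation (times are heavily tied across samples, so the exact
#' permutation distribution does not apply).
#'
#' @param table A [sample_table()] whose samples carry `time_h`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame with `analyte`, `rho`, `p`, `significant`.
#' @export
spearman_time <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "sample_table"))
  t_h <- table$meta$time_h
  keep <- !is.na(t_h)
  if (length(unique(t_h[keep])) < 2) {
    stop("need at least 2 distinct time points")
  }
  X <- table$X[keep, , drop = FALSE]
  t_h <- t_h[keep]
  res <- lapply(colnames(X), function(code) {
    ct <- suppressWarnings(
      stats::cor.test(X[, code], t_h, method = "spearman", exact = FALSE))
    data.frame(analyte = code, rho = unname(ct$estimate),
               p = unname(ct$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out
}

#' PCA on selected analytes
#'
#' Principal component analysis of the autoscaled (centered, unit-variance)
#' concentrations of a selection of analytes, typically those significant
#' in at least one pairwise comparison. Zero-variance analytes are dropped
#' with a warning and recorded in the result.
#'
#' @param table A [sample_table()].
#' @param selection Character vector of analyte codes (>= 2 usable).
#' @return List of class `pca_result`: `loadings` (analytes x PCs,
#'   orthonormal), `scores` (samples x PCs), `explained` (variance
#'   fractions, non-increasing), `analytes`, `dropped`.
#' @export
pca_on_significant <- function(table, selection) {
  stopifnot(inherits(table, "sample_table"))
  unknown <- setdiff(selection, colnames(table$X))
  if (length(unknown)) stop("unknown analyte in selection: ", unknown[1])
  X <- table$X[, selection, drop = FALSE]
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance analyte(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need at least 2 analytes with variance")
  if (nrow(X) < 3) stop("need at least 3 samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(loadings = pc$rotation,
                 scores = pc$x,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 analytes = colnames(X),
                 dropped = dropped),
            class = "pca_result")
}
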