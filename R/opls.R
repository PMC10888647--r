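#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' Fits a binary OPLS-DA model: `n_ortho` orthogonal (class-unrelated)
#' components are extracted sequentially by orthogonal signal correction —
#' each one is the part of the current PLS loading not collinear with the
#' y-correlated weight — and removed from X, after which a single
#' predictive PLS component is fitted on the filtered matrix. With
#' `n_ortho = 0` the model is numerically identical to one-component PLS1.
#'
#' Columns are autoscaled (`scale = "uv"`, unit variance) or Pareto-scaled
#' (`"pareto"`, divide by the square root of the standard deviation); y is
#' centered. R2X is the fraction of the scaled X sum of squares captured by
#' all modeled components, R2Y the fraction of the centered y sum of
#' squares described by the predictive component, and Q2 (from
#' [loo_cv_opls()]) the fraction predicted under cross-validation.
#'
#' VIP scores are computed over the predictive plus orthogonal components,
#' each component's squared normalized weights weighted by the y sum of
#' squares it explains, so that `mean(VIP^2) = 1`; `vip_mode = "pred"`
#' restricts to the predictive component.
#'
#' @param X Numeric matrix, samples x variables; no zero-variance columns.
#' @param y Binary 0/1 vector (both classes with >= 2 samples).
#' @param n_ortho Number of orthogonal components (>= 0, < rank of scaled X).
#' @param scale `"uv"` (default) or `"pareto"`.
#' @param vip_mode `"all"` (default) or `"pred"`.
#' @return An object of class `opls_model`.
#' @export
fit_opls <- function(X, y, n_ortho = 0, scale = c("uv", "pareto"),
                     vip_mode = c("all", "pred")) {
  scale <- match.arg(scale)
  vip_mode <- match.arg(vip_mode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (sum(y == 0) < 2 || sum(y == 1) < 2) {
    stop("each class needs at least 2 samples")
  }
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  xs_sd <- apply(X, 2, stats::sd)
  if (any(xs_sd == 0)) {
    stop("zero-variance column: ", colnames(X)[which(xs_sd == 0)[1]])
  }
  xm <- colMeans(X)
  xs <- if (scale == "uv") xs_sd else sqrt(xs_sd)
  E <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  rk <- qr(E)$rank
  if (n_ortho >= rk) stop("n_ortho must be below rank(X) = ", rk)
  totX <- sum(E^2)
  totY <- sum(yc^2)
  p_vars <- ncol(X)
  W_o <- P_o <- matrix(0, p_vars, 0)
  T_o <- matrix(0, nrow(X), 0)
  ssx_o <- ssy_o <- numeric(0)
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(E, yc)) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    t_p <- drop(E %*% w)
    p_l <- drop(crossprod(E, t_p)) / sum(t_p^2)
    w_o <- p_l - sum(w * p_l) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) stop("no orthogonal variation left at component ", k)
    w_o <- w_o / nw
    t_o <- drop(E %*% w_o)
    p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    ssx_o <- c(ssx_o, sum(t_o^2) * sum(p_o^2))
    ssy_o <- c(ssy_o, sum(yc * t_o)^2 / sum(t_o^2))
  }
  w <- drop(crossprod(E, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  t_p <- drop(E %*% w)
  p_l <- drop(crossprod(E, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  ssx_p <- sum(t_p^2) * sum(p_l^2)
  ssy_p <- q^2 * sum(t_p^2)
  residX <- sum(E^2) - ssx_p
  vip <- vip_scores(w, W_o, ssy_p, ssy_o, vip_mode)
  model <- structure(list(
    xm = xm, xs = xs, scale = scale, ym = ym,
    w = w, p = p_l, t = t_p, q = q,
    W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = n_ortho,
    R2X = (ssx_p + sum(ssx_o)) / totX,
    R2Y = ssy_p / totY,
    ssx = c(pred = ssx_p, ortho = ssx_o), ssx_residual = residX,
    ssx_total = totX,
    VIP = vip, vip_mode = vip_mode,
    variables = colnames(X), cutoff = NULL),
    class = "opls_model")
  model
}

vip_scores <- function(w, W_o, ssy_p, ssy_o, vip_mode) {
  p_vars <- length(w)
  if (vip_mode == "pred" || ncol(W_o) == 0) {
    Wmat <- matrix(w, ncol = 1)
    ssy <- ssy_p
  } else {
    Wmat <- cbind(w, W_o)
    ssy <- c(ssy_p, ssy_o)
  }
  vip <- sqrt(p_vars * drop(Wmat^2 %*% ssy) / sum(ssy))
  names(vip) <- names(w)
  vip
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal component(s)\n",
              x$n_ortho))
  cat(sprintf("  R2X = %.3f, R2Y = %.3f\n", x$R2X, x$R2Y))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' @param object An `opls_model`.
#' @param newdata Numeric matrix with the model's variables as columns.
#' @param type `"response"` (predicted y-hat, default) or `"score"`
#'   (predictive score t).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.opls_model <- function(object, newdata,
                               type = c("response", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$variables) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$variables, drop = FALSE]
  }
  E <- sweep(sweep(newdata, 2, object$xm), 2, object$xs, "/")
  for (k in seq_len(object$n_ortho)) {
    t_o <- drop(E %*% object$W_o[, k])
    E <- E - tcrossprod(t_o, object$P_o[, k])
  }
  t_new <- drop(E %*% object$w)
  if (type == "score") return(t_new)
  object$ym + t_new * object$q
}

#' Leave-one-out cross-validation of an OPLS-DA model
#'
#' Each sample is left out in turn, the model refitted on the rest
#' (including re-centering and re-scaling) and the held-out y-hat
#' predicted. `Q2 = 1 - PRESS / sum((y - mean(y))^2)`. Folds whose training
#' set loses an entire class are skipped with a warning and recorded.
#'
#' @inheritParams fit_opls
#' @return List with `Q2`, `cv_scores` (held-out y-hat per sample; `NA`
#'   for skipped folds) and `skipped` (indices).
#' @export
loo_cv_opls <- function(X, y, n_ortho = 0, scale = c("uv", "pareto")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 samples for LOO")
  cv <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (sum(ytr == 0) < 2 || sum(ytr == 1) < 2) {
      warning("fold ", i, " leaves fewer than 2 samples in a class; skipped")
      skipped <- c(skipped, i)
      next
    }
    fit <- fit_opls(X[-i, , drop = FALSE], ytr, n_ortho = n_ortho,
                    scale = scale)
    cv[i] <- predict(fit, X[i, , drop = FALSE])
  }
  ok <- !is.na(cv)
  press <- sum((y[ok] - cv[ok])^2)
  ss <- sum((y[ok] - mean(y))^2)
  list(Q2 = 1 - press / ss, cv_scores = cv, skipped = skipped)
}
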