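#' Quadratic feature expansion of a concentration matrix
#'
#' Builds the expanded candidate-feature set for the diagnostic logistic
#' model: the base concentrations, their squares, and the pairwise products
#' of every analyte pair. For `p` base analytes the expansion has
#' `2p + p(p-1)/2` features, ordered deterministically: bases in panel
#' order, then squares (`"code^2"`), then products (`"a*b"`) in
#' lexicographic pair order of the base ordering.
#'
#' @param table A [sample_table()] or a numeric matrix with analyte columns.
#' @return List of class `expanded_features`: `matrix` (samples x
#'   features), `base_codes`, `provenance` (named list: base analytes each
#'   feature derives from).
#' @export
expand_features <- function(table) {
  X <- if (inherits(table, "sample_table")) table$X else as.matrix(table)
  if (is.null(colnames(X))) stop("matrix must carry analyte column names")
  codes <- colnames(X)
  p <- length(codes)
  sq <- X^2
  colnames(sq) <- paste0(codes, "^2")
  prov <- c(as.list(codes), as.list(codes))
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    prod_mat <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(prod_mat) <- paste0(codes[pairs[1, ]], "*", codes[pairs[2, ]])
    prov <- c(prov, lapply(seq_len(ncol(pairs)),
                           function(j) codes[pairs[, j]]))
  } else {
    prod_mat <- X[, 0, drop = FALSE]
  }
  M <- cbind(X, sq, prod_mat)
  names(prov) <- colnames(M)
  structure(list(matrix = M, base_codes = codes, provenance = prov),
            class = "expanded_features")
}

#' @export
print.expanded_features <- function(x, ...) {
  cat(sprintf("<expanded_features> %d samples x %d features (%d base analytes)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$base_codes)))
  invisible(x)
}

# treat a plain matrix as a ready-made candidate set (each column its own
# feature); quadratic expansion only ever happens via expand_features()
as_feature_set <- function(features) {
  if (inherits(features, "expanded_features")) return(features)
  M <- as.matrix(features)
  if (is.null(colnames(M))) stop("matrix must carry feature column names")
  structure(list(matrix = M, base_codes = colnames(M),
                 provenance = stats::setNames(as.list(colnames(M)),
                                              colnames(M))),
            class = "expanded_features")
}

subset_features <- function(features, keep) {
  structure(list(matrix = features$matrix[, keep, drop = FALSE],
                 base_codes = features$base_codes,
                 provenance = features$provenance[keep]),
            class = "expanded_features")
}

#' VIP > 1 prefilter of the candidate features
#'
#' Fits an OPLS-DA model ([fit_opls()]) on the expanded feature matrix and
#' keeps the features with VIP above the threshold — the preliminary marker
#' set of the diagnostic-model builder. Constant features (possible inside
#' small CV folds) are dropped before the fit.
#'
#' @param features An [expand_features()] object, or a numeric matrix whose
#'   columns are used as candidate features as-is.
#' @param y Binary 0/1 outcome.
#' @param n_ortho Orthogonal components for the filter model (default 2).
#' @param threshold VIP threshold (default 1).
#' @return The surviving features as an `expanded_features` object, with
#'   the VIP values attached as attribute `"vip"`.
#' @export
vip_prefilter <- function(features, y, n_ortho = 2, threshold = 1) {
  features <- as_feature_set(features)
  M <- features$matrix
  ok <- apply(M, 2, stats::sd) > 0
  fit <- fit_opls(M[, ok, drop = FALSE], y, n_ortho = n_ortho)
  keep <- names(fit$VIP)[fit$VIP > threshold]
  if (!length(keep)) stop("no features passed VIP filter")
  out <- subset_features(features, keep)
  attr(out, "vip") <- fit$VIP[keep]
  out
}

# logistic fit on a design matrix (intercept added), with separation
# detection and a ridge-stabilized fallback; se = FALSE skips the Wald
# covariance work for fast AIC-only candidate scans
fit_logistic <- function(Xm, y, ridge_lambda = 1e-2, se = TRUE) {
  Xd <- cbind("(Intercept)" = 1, Xm)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged ||
    (any(mu > 1 - 1e-6) || any(mu < 1e-6)) && max(abs(fit$coefficients)) > 15
  coefs <- fit$coefficients
  if (!se) {
    return(list(coefficients = coefs, aic = fit$aic,
                deviance = fit$deviance, separated = separated))
  }
  if (separated) {
    coefs <- ridge_logistic(Xd, y, lambda = ridge_lambda)
    mu <- drop(stats::plogis(Xd %*% coefs))
  }
  W <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(Xd * sqrt(W))
  if (separated) diag(XtWX) <- diag(XtWX) + ridge_lambda
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    MASS::ginv(XtWX)
  })
  se_vec <- sqrt(pmax(diag(V), 0))
  z <- coefs / se_vec
  list(coefficients = coefs,
       wald_p = 2 * stats::pnorm(-abs(z)),
       aic = fit$aic,
       deviance = fit$deviance,
       separated = separated,
       fitted = mu)
}

# drop-one likelihood-ratio p-values; the well-behaved replacement for Wald
# tests when the fit is separation-flagged (Hauck-Donner: the Wald statistic
# of a perfect separator collapses toward 0)
drop_one_lr_p <- function(M, kept, y, dev_full) {
  vapply(kept, function(f) {
    reduced <- fit_logistic(M[, setdiff(kept, f), drop = FALSE], y, se = FALSE)
    stats::pchisq(max(reduced$deviance - dev_full, 0), df = 1,
                  lower.tail = FALSE)
  }, 0)
}

# penalized IRLS (ridge on all coefficients incl. intercept kept unpenalized)
ridge_logistic <- function(Xd, y, lambda = 1e-2, maxit = 100, tol = 1e-9) {
  beta <- rep(0, ncol(Xd))
  pen <- c(0, rep(lambda, ncol(Xd) - 1))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    H <- crossprod(Xd * sqrt(W))
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(Xd))
}

#' Forward stepwise logistic selection by AIC
#'
#' Starting from the intercept-only model, the candidate feature whose
#' addition lowers AIC the most is added at each step; selection stops when
#' no addition decreases AIC. Perfect separation at an accepted step is
#' tolerated: the step is kept with a ridge-stabilized fit and the flag
#' recorded.
#'
#' @param features [expand_features()] object or numeric matrix of
#'   candidates.
#' @param y Binary 0/1 outcome (n >= 6).
#' @return List of class `stepwise_fit`: `selected` (feature names in
#'   selection order), `fit` (final [fit_logistic()] result), `path` (data
#'   frame of the AIC trajectory), `matrix` (selected columns), `y`.
#' @export
stepwise_aic <- function(features, y) {
  M <- if (inherits(features, "expanded_features")) features$matrix else as.matrix(features)
  y <- as.numeric(y)
  if (length(y) < 6) stop("need at least 6 samples")
  if (!ncol(M)) stop("no candidate features")
  null_fit <- fit_logistic(M[, 0, drop = FALSE], y)
  aic_cur <- null_fit$aic
  selected <- character(0)
  path <- data.frame(step = 0L, feature = "(intercept)", aic = aic_cur,
                     stringsAsFactors = FALSE)
  remaining <- colnames(M)
  repeat {
    if (!length(remaining)) break
    aics <- vapply(remaining, function(f) {
      fit_logistic(M[, c(selected, f), drop = FALSE], y, se = FALSE)$aic
    }, 0)
    best <- names(aics)[which.min(aics)]
    if (min(aics) >= aic_cur - 1e-8) break
    selected <- c(selected, best)
    aic_cur <- min(aics)
    path <- rbind(path, data.frame(step = length(selected), feature = best,
                                   aic = aic_cur, stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, best)
  }
  fit <- fit_logistic(M[, selected, drop = FALSE], y)
  structure(list(selected = selected, fit = fit, path = path,
                 matrix = M[, selected, drop = FALSE], y = y),
            class = "stepwise_fit")
}

#' Backward elimination by coefficient p-value
#'
#' Starting from a [stepwise_aic()] fit, the feature whose coefficient has
#' the largest p-value for the zero-equality test is dropped (intercept
#' exempt) and the model refitted, until every remaining coefficient has
#' p below `alpha`. Wald tests are used for regular fits; when a fit is
#' separation-flagged the Wald statistic of the separating feature
#' collapses toward zero (Hauck-Donner effect), so drop-one
#' likelihood-ratio tests are substituted (`p_type` records which was
#' used). If everything is eliminated, the intercept-only model is
#' returned with a warning.
#'
#' @param model A `stepwise_fit`.
#' @param alpha Significance level (default 0.05).
#' @param p_type `"auto"` (Wald, switching to likelihood-ratio under
#'   separation; default), `"wald"`, or `"lr"`.
#' @return List of class `dx_logistic_model`: `features`, `coefficients`,
#'   `p_values` (per retained feature), `p_type`, `wald_p`, `separated`,
#'   `forward_path`, `elimination_path`, `fitted`, `y`.
#' @export
backward_p_elimination <- function(model, alpha = 0.05,
                                   p_type = c("auto", "wald", "lr")) {
  stopifnot(inherits(model, "stepwise_fit"))
  p_type <- match.arg(p_type)
  M <- model$matrix
  y <- model$y
  kept <- model$selected
  fit <- model$fit
  dropped <- character(0)
  feature_p <- function(fit, kept) {
    use_lr <- p_type == "lr" || (p_type == "auto" && fit$separated)
    if (!length(kept)) return(numeric(0))
    if (use_lr) drop_one_lr_p(M, kept, y, fit$deviance) else fit$wald_p[kept]
  }
  p_feat <- feature_p(fit, kept)
  while (length(kept)) {
    if (max(p_feat) < alpha) break
    worst <- kept[which.max(p_feat)]
    dropped <- c(dropped, worst)
    kept <- setdiff(kept, worst)
    fit <- fit_logistic(M[, kept, drop = FALSE], y)
    p_feat <- feature_p(fit, kept)
  }
  if (!length(kept)) {
    warning("all features eliminated; returning intercept-only model")
  }
  used_lr <- p_type == "lr" || (p_type == "auto" && fit$separated)
  structure(list(features = kept,
                 coefficients = fit$coefficients,
                 p_values = p_feat,
                 p_type = if (used_lr) "lr" else "wald",
                 wald_p = fit$wald_p,
                 separated = fit$separated,
                 forward_path = model$path,
                 elimination_path = dropped,
                 fitted = fit$fitted,
                 y = y),
            class = "dx_logistic_model")
}

#' @export
print.dx_logistic_model <- function(x, ...) {
  cat("<dx_logistic_model>",
      if (length(x$features)) paste(x$features, collapse = " + ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Predicted probabilities from a diagnostic logistic model
#'
#' @param object A `dx_logistic_model`.
#' @param newdata An [expand_features()] object or matrix containing the
#'   model's feature columns.
#' @param ... Unused.
#' @return Vector of predicted probabilities.
#' @export
predict.dx_logistic_model <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "expanded_features")) newdata$matrix else as.matrix(newdata)
  Xd <- cbind(1, M[, object$features, drop = FALSE])
  drop(stats::plogis(Xd %*% object$coefficients))
}

#' Full diagnostic-model builder
#'
#' Chains the three construction stages on an expanded feature set:
#' VIP > 1 prefilter ([vip_prefilter()]), forward AIC selection
#' ([stepwise_aic()]), and backward Wald-p elimination
#' ([backward_p_elimination()]).
#'
#' @inheritParams vip_prefilter
#' @param alpha Wald level for the elimination stage.
#' @return A `dx_logistic_model` (with the surviving VIP set attached as
#'   attribute `"vip_survivors"`).
#' @export
build_dx_model <- function(features, y, n_ortho = 2, vip_threshold = 1,
                           alpha = 0.05) {
  features <- as_feature_set(features)
  survivors <- vip_prefilter(features, y, n_ortho = n_ortho,
                             threshold = vip_threshold)
  model <- backward_p_elimination(stepwise_aic(survivors, y), alpha = alpha)
  attr(model, "vip_survivors") <- colnames(survivors$matrix)
  model
}

#' Leave-one-out cross-validation of the diagnostic-model builder
#'
#' The entire builder — prefilter, AIC selection, elimination — is re-run
#' inside each fold, so no information from the held-out sample reaches
#' feature selection. Held-out probabilities are pooled for the ROC curve;
#' the cutoff is chosen by Youden's J on those cross-validated
#' probabilities.
#'
#' @inheritParams build_dx_model
#' @return List: `cv_prob` (held-out probability per sample), `roc`, `auc`,
#'   `cutoff`, `sensitivity`, `specificity`, `skipped` (failed folds).
#' @export
loo_cv_logit <- function(features, y, n_ortho = 2, vip_threshold = 1,
                         alpha = 0.05) {
  features <- as_feature_set(features)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 6) stop("need at least 6 samples")
  cv <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (sum(ytr == 0) < 2 || sum(ytr == 1) < 2) {
      skipped <- c(skipped, i)
      next
    }
    res <- tryCatch({
      train <- subset_features(features, colnames(features$matrix))
      train$matrix <- train$matrix[-i, , drop = FALSE]
      m <- build_dx_model(train, ytr, n_ortho = n_ortho,
                          vip_threshold = vip_threshold, alpha = alpha)
      predict(m, features$matrix[i, , drop = FALSE])
    }, error = function(e) NA_real_)
    if (is.na(res)) skipped <- c(skipped, i) else cv[i] <- res
  }
  ok <- !is.na(cv)
  if (sum(ok) < 4 || length(unique(y[ok])) < 2) {
    stop("too few successful folds for cross-validated ROC")
  }
  rc <- roc(cv[ok], y[ok])
  yj <- youden_cutoff(cv[ok], y[ok])
  list(cv_prob = cv, roc = rc, auc = rc$auc, cutoff = yj$cutoff,
       sensitivity = yj$sensitivity, specificity = yj$specificity,
       skipped = skipped)
}

#' Repeated stratified train/test split validation
#'
#' Pools the negative- and positive-class samples of a table (typically
#' controls and 6 h hypoxia-ischemia animals from two experiments) and
#' repeats `n_repeats` stratified 70/30 train/test splits. On each train
#' split both diagnostic models are rebuilt — the OPLS-DA classifier on the
#' analyte concentrations and the logistic builder on the expanded features
#' — with their cutoffs chosen by Youden's J on the training scores, and
#' sensitivity/specificity are measured on the test split. Degenerate
#' splits (a class missing from train or test) are redrawn and counted.
#'
#' @param table A [sample_table()] containing both groups.
#' @param group_neg,group_pos Group labels for the negative (control) and
#'   positive (case) class; several labels may be given per class.
#' @param n_repeats Number of splits (default 100).
#' @param frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param n_ortho Orthogonal components for the OPLS classifier (default 4)
#'   and the VIP prefilter.
#' @param alpha Wald level for the logistic elimination stage.
#' @return List of class `split_validation_report`: `per_repeat` (data
#'   frame of per-split metrics for both models), `means`, `n_redrawn`,
#'   `n_repeats`, `frac`, `seed`.
#' @export
split_validation <- function(table, group_neg, group_pos, n_repeats = 100,
                             frac = 0.7, seed = 1, n_ortho = 4,
                             alpha = 0.05) {
  stopifnot(inherits(table, "sample_table"))
  sub <- subset_groups(table, c(group_neg, group_pos))
  y <- as.numeric(sub$meta$group %in% group_pos)
  X <- sub$X
  features <- expand_features(sub)
  n <- length(y)
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  with_seed(seed, {
    rows <- vector("list", n_repeats)
    n_redrawn <- 0L
    for (r in seq_len(n_repeats)) {
      repeat {
        tr <- c(sample(idx_pos, round(frac * length(idx_pos))),
                sample(idx_neg, round(frac * length(idx_neg))))
        te <- setdiff(seq_len(n), tr)
        if (length(unique(y[tr])) == 2 && length(unique(y[te])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      opls <- fit_opls(X[tr, , drop = FALSE], y[tr], n_ortho = n_ortho)
      # cutoff from the training split's LOO-CV scores: refit scores are
      # optimistically spread and would push the cutoff past the test scores
      cv_o <- suppressWarnings(
        loo_cv_opls(X[tr, , drop = FALSE], y[tr], n_ortho = n_ortho))
      ok_o <- !is.na(cv_o$cv_scores)
      cut_o <- youden_cutoff(cv_o$cv_scores[ok_o], y[tr][ok_o])$cutoff
      te_scores <- predict(opls, X[te, , drop = FALSE])
      perf_o <- classify_at_cutoff(te_scores, y[te], cut_o)
      perf_l <- tryCatch({
        ftr <- subset_features(features, colnames(features$matrix))
        ftr$matrix <- ftr$matrix[tr, , drop = FALSE]
        m <- build_dx_model(ftr, y[tr], n_ortho = n_ortho, alpha = alpha)
        cut_l <- youden_cutoff(predict(m, features$matrix[tr, , drop = FALSE]),
                               y[tr])$cutoff
        classify_at_cutoff(predict(m, features$matrix[te, , drop = FALSE]),
                           y[te], cut_l)
      }, error = function(e) list(sensitivity = NA_real_,
                                  specificity = NA_real_))
      rows[[r]] <- data.frame(
        repeat_id = r,
        opls_sensitivity = perf_o$sensitivity,
        opls_specificity = perf_o$specificity,
        logit_sensitivity = perf_l$sensitivity,
        logit_specificity = perf_l$specificity)
    }
    per_repeat <- do.call(rbind, rows)
    means <- colMeans(per_repeat[, -1], na.rm = TRUE)
    structure(list(per_repeat = per_repeat, means = means,
                   n_redrawn = n_redrawn, n_repeats = n_repeats,
                   frac = frac, seed = seed),
              class = "split_validation_report")
  })
}

#' @export
print.split_validation_report <- function(x, ...) {
  cat(sprintf("<split_validation_report> %d stratified %.0f/%.0f splits\n",
              x$n_repeats, 100 * x$frac, 100 * (1 - x$frac)))
  print(round(x$means, 3))
  invisible(x)
}
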