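test_that("feature expansion has the documented size and ordering", {
  tab <- planted_cohort(1, n_a = 3, n_b = 3)           # full 57-analyte panel
  f <- expand_features(tab)
  expect_equal(ncol(f$matrix), 57 + 57 + choose(57, 2))  # 1710
  expect_equal(ncol(f$matrix), 1710)

  sm <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  fs <- expand_features(sm)
  expect_equal(colnames(fs$matrix), c("a", "b", "a^2", "b^2", "a*b"))
  expect_equal(fs$matrix[, "a*b"], sm[, "a"] * sm[, "b"])
  expect_equal(fs$provenance[["a*b"]], c("a", "b"))

  tab_sq <- expand_features(planted_cohort(2, panel = small_panel(),
                                           n_a = 4, n_b = 4))
  expect_equal(tab_sq$matrix[, "glycine^2"],
               tab_sq$matrix[, "glycine"]^2)
})

test_that("the VIP prefilter keeps planted glycine terms and bounds survivors", {
  keeps <- vapply(1:20, function(s) {
    tab <- planted_cohort(s, panel = small_panel(), fold = c(glycine = 2.5),
                          n_a = 10, n_b = 12)
    y <- as.numeric(tab$meta$group == "b")
    surv <- vip_prefilter(expand_features(tab), y, n_ortho = 1)
    all(c("glycine", "glycine^2") %in% colnames(surv$matrix))
  }, NA)
  expect_gte(sum(keeps), 18)

  set.seed(21)
  Xn <- matrix(rnorm(23 * 40), 23, 40,
               dimnames = list(NULL, sprintf("n%02d", 1:40)))
  y <- rep(c(0, 1), times = c(11, 12))
  surv <- vip_prefilter(Xn, y, n_ortho = 1)
  expect_lt(ncol(surv$matrix) / 40, 0.6)   # mean(VIP^2)=1 pigeonhole
  expect_equal(colnames(surv$matrix),
               intersect(colnames(Xn), colnames(surv$matrix)))

  expect_error(vip_prefilter(Xn, y, threshold = 1e6), "no features passed")
})

test_that("forward AIC selection recovers a planted quadratic term", {
  first_is_g2 <- vapply(1:20, function(s) {
    set.seed(s)
    g <- exp(rnorm(40, 5, 0.4))
    junk <- matrix(exp(rnorm(40 * 5, 1, 0.5)), 40, 5,
                   dimnames = list(NULL, sprintf("j%d", 1:5)))
    eta <- -25 + 1.1e-3 * g^2
    y <- rbinom(40, 1, plogis(eta))
    if (length(unique(y)) < 2) return(NA)
    M <- expand_features(cbind(g = g, junk))
    st <- stepwise_aic(M, y)
    length(st$selected) >= 1 && grepl("^g", st$selected[1])
  }, NA)
  expect_gte(sum(first_is_g2, na.rm = TRUE), 16)
})

test_that("AIC decreases strictly along the forward path and stops under null", {
  tab <- planted_cohort(3, panel = small_panel(), fold = c(glycine = 2),
                        n_a = 10, n_b = 12)
  y <- as.numeric(tab$meta$group == "b")
  st <- stepwise_aic(expand_features(tab), y)
  expect_true(all(diff(st$path$aic) < 0))
  expect_gte(length(st$selected), 1)

  set.seed(31)
  n_selected <- vapply(1:100, function(i) {
    Xn <- matrix(rnorm(30 * 3), 30, 3,
                 dimnames = list(NULL, c("n1", "n2", "n3")))
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) return(NA_integer_)
    length(stepwise_aic(Xn, y)$selected)
  }, 1L)
  expect_lte(median(n_selected, na.rm = TRUE), 1)
})

test_that("backward elimination drops junk and keeps real effects", {
  set.seed(41)
  n <- 60
  x_real <- rnorm(n)
  x_junk <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x_real))
  M <- cbind(real = x_real, junk = x_junk)
  st <- structure(list(selected = c("real", "junk"),
                       fit = neodx:::fit_logistic(M, y),
                       path = data.frame(step = 0:2,
                                         feature = c("(intercept)", "real",
                                                     "junk"),
                                         aic = c(3, 2, 1)),
                       matrix = M, y = y),
                  class = "stepwise_fit")
  m <- backward_p_elimination(st)
  expect_equal(m$features, "real")
  expect_equal(m$elimination_path, "junk")
  expect_true(all(m$p_values < 0.05))
  expect_lte(length(m$elimination_path), 2)

  # fixed point: a model whose features are all significant is unchanged
  st2 <- structure(list(selected = "real",
                        fit = neodx:::fit_logistic(M[, "real", drop = FALSE], y),
                        path = st$path[1:2, ], matrix = M[, "real", drop = FALSE],
                        y = y),
                   class = "stepwise_fit")
  m2 <- backward_p_elimination(st2)
  expect_equal(m2$features, "real")
  expect_equal(m2$elimination_path, character(0))
})

test_that("separated fits are flagged, stabilized and survive elimination", {
  x <- c(1:6, 10:15)
  y <- rep(c(0, 1), each = 6)
  M <- cbind(sep = x)
  fit <- neodx:::fit_logistic(M, y)
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
  st <- stepwise_aic(M, y)
  m <- backward_p_elimination(st)
  expect_equal(m$features, "sep")
  expect_equal(m$p_type, "lr")
})

test_that("logistic MLE matches the contingency-table log-odds on a 2x2", {
  x <- rep(c(0, 1), times = c(40, 40))
  set.seed(51)
  y <- c(rbinom(40, 1, 0.25), rbinom(40, 1, 0.75))
  fit <- neodx:::fit_logistic(cbind(x = x), y)
  expect_false(fit$separated)
  p0 <- mean(y[x == 0]); p1 <- mean(y[x == 1])
  expect_equal(unname(fit$coefficients["x"]),
               log(p1 / (1 - p1)) - log(p0 / (1 - p0)), tolerance = 1e-6)
})

test_that("the full builder selects a glycine-derived model on strong data", {
  tab <- planted_cohort(61, panel = small_panel(), fold = c(glycine = 2.5),
                        n_a = 10, n_b = 12)
  y <- as.numeric(tab$meta$group == "b")
  f <- expand_features(tab)
  m <- build_dx_model(f, y, n_ortho = 1)
  expect_gte(length(m$features), 1)
  prov <- unique(unlist(f$provenance[m$features]))
  expect_true("glycine" %in% prov)
})

test_that("cross-validated logistic metrics behave on signal and null", {
  tab <- planted_cohort(71, panel = small_panel(), fold = c(glycine = 2.5),
                        n_a = 10, n_b = 12)
  y <- as.numeric(tab$meta$group == "b")
  f <- expand_features(tab)
  cv <- loo_cv_logit(f, y, n_ortho = 1)
  expect_gt(cv$auc, 0.8)
  expect_gte(cv$sensitivity, 0.7)
  expect_gte(cv$specificity, 0.7)

  # with permuted labels the cross-validated AUC must show no optimistic
  # signal (whole-builder-inside-the-fold: no leakage into selection); the
  # LOO estimate is pessimistically biased under the null, so only the
  # upper tail is informative
  set.seed(81)
  null_aucs <- vapply(1:20, function(i) {
    yp <- sample(y)
    suppressWarnings(
      tryCatch(loo_cv_logit(f, yp, n_ortho = 1)$auc, error = function(e) NA))
  }, 0)
  expect_lte(mean(null_aucs > 0.7, na.rm = TRUE), 0.2)
  expect_lte(median(null_aucs, na.rm = TRUE), 0.6)
})

test_that("fold models never see the held-out sample's label", {
  # swapping the held-out label cannot change the fold's trained model
  tab <- planted_cohort(91, panel = small_panel(), fold = c(glycine = 2),
                        n_a = 8, n_b = 8)
  y <- as.numeric(tab$meta$group == "b")
  f <- expand_features(tab)
  i <- 1
  train <- f
  train$matrix <- f$matrix[-i, , drop = FALSE]
  m1 <- build_dx_model(train, y[-i], n_ortho = 1)
  y_flip <- y; y_flip[i] <- 1 - y_flip[i]
  m2 <- build_dx_model(train, y_flip[-i], n_ortho = 1)
  expect_identical(m1$features, m2$features)
  expect_equal(m1$coefficients, m2$coefficients)
})

test_that("split validation is deterministic and recovers strong effects", {
  tab <- planted_cohort(101, panel = small_panel(), fold = c(glycine = 3),
                        n_a = 23, n_b = 26)
  r1 <- split_validation(tab, "a", "b", n_repeats = 20, seed = 5, n_ortho = 1)
  r2 <- split_validation(tab, "a", "b", n_repeats = 20, seed = 5, n_ortho = 1)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_true(all(unlist(r1$per_repeat[, -1]) >= 0 &
                    unlist(r1$per_repeat[, -1]) <= 1, na.rm = TRUE))
  expect_gt(r1$means[["opls_sensitivity"]], 0.8)
  expect_gt(r1$means[["opls_specificity"]], 0.8)
  expect_gt(r1$means[["logit_sensitivity"]], 0.8)
  expect_gt(r1$means[["logit_specificity"]], 0.8)
})
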