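# Independent brute-force oracles used to pin down the statistical
# primitives. These are deliberately naive re-derivations (enumeration,
# direct formulas) and share no code with the package internals.

# exact two-sided Mann-Whitney p by full enumeration of group labelings
mw_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  count_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- count_u(x, y)
  idx <- utils::combn(n + m, n)
  us <- apply(idx, 2, function(ii) count_u(pooled[ii], pooled[-ii]))
  p_low <- mean(us <= u_obs + 1e-9)
  p_high <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# hypergeometric upper tail by exhaustive enumeration of marker draws
hyper_enum_oracle <- function(N, K, n, hits) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= hits)
}

# mean silhouette width from the definition (singletons get width 0)
silhouette_oracle <- function(labels, D) {
  n <- length(labels)
  widths <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, 0))
    (b - a) / max(a, b)
  }, 0)
  mean(widths)
}

# one-component PLS1 with autoscaled X and centered y, from the formulas
pls1_oracle <- function(X, y, newdata = X) {
  xm <- colMeans(X)
  xs <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yc <- y - mean(y)
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  q <- sum(yc * t) / sum(t^2)
  Ns <- sweep(sweep(as.matrix(newdata), 2, xm), 2, xs, "/")
  mean(y) + drop(Ns %*% w) * q
}

# ---- small fixtures built in code ------------------------------------------

# a compact real-compound panel so expansion stays small in module tests
small_panel <- function() {
  metabolite_panel(
    code = c("glycine", "alanine", "methionine", "glutamate", "Gln/Lys",
             "C2", "C3", "C4"),
    class = c(rep("amino_acid", 5), rep("acylcarnitine", 3)),
    variants = list("glycine", "alanine", "methionine", "glutamate",
                    c("glutamine", "lysine"), "acetylcarnitine",
                    "propionylcarnitine", "butyrylcarnitine"))
}

# two-group cohort with an effect planted on chosen analytes
planted_cohort <- function(seed, fold = c(glycine = 2), n_a = 10, n_b = 12,
                           panel = default_panel(), sdlog = 0.3,
                           blocks = NULL, blocks_b = NULL) {
  tpl <- effect_template("planted", list(
    list(name = "a", n = n_a, time_h = 0, treatment = "none"),
    list(name = "b", n = n_b, time_h = 6, treatment = "HIE", fold = fold,
         blocks = blocks_b)))
  generate_cohort(tpl, noise_model(panel, sdlog = sdlog, blocks = blocks),
                  seed = seed, panel = panel)
}
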