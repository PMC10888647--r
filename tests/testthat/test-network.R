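# a compact anonymous panel for clean planted-partition constructions
toy_panel <- function(n) {
  metabolite_panel(sprintf("m%02d", seq_len(n)), rep("amino_acid", n),
                   as.list(sprintf("compound%02d", seq_len(n))))
}

toy_rewired <- function(seed, n_per_group = 200, n_analytes = 9,
                        blocks_b = list(list(codes = c("m01", "m02", "m03"),
                                             rho = 0.8))) {
  panel <- toy_panel(n_analytes)
  tpl <- effect_template("rewire", list(
    list(name = "a", n = n_per_group),
    list(name = "b", n = n_per_group, blocks = blocks_b)))
  # group a keeps independent analytes; group b gains the planted blocks
  generate_cohort(tpl, noise_model(panel, blocks = list()),
                  seed = seed, panel = panel)
}

test_that("identical groups give a zero change matrix and no-rewiring flag", {
  tab <- planted_cohort(1, panel = small_panel(), n_a = 6, n_b = 6)
  dup <- tab
  dup$X[tab$meta$group == "b", ] <- dup$X[tab$meta$group == "a", ]
  ch <- adjacency_change(dup, "a", "b")
  expect_true(ch$no_rewiring)
  expect_equal(max(ch$C), 0)
  expect_null(ch$D)
  expect_error(ward_silhouette(ch), "no rewiring")
})

test_that("adjacency and change matrices respect their ranges", {
  tab <- toy_rewired(2, n_per_group = 30)
  ch <- adjacency_change(tab, "a", "b")
  for (M in list(ch$A1, ch$A2)) {
    expect_equal(M, t(M))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(diag(M)), rep(1, ncol(M)))
  }
  expect_equal(ch$C, t(ch$C))
  expect_true(all(ch$C >= 0 & ch$C <= 1))
  expect_equal(unname(diag(ch$C)), rep(0, ncol(ch$C)))
  expect_true(all(ch$D >= 0 & ch$D <= 1))
  expect_equal(unname(diag(ch$D)), rep(0, ncol(ch$D)))
  expect_error(adjacency_change(tab, "a", "nope"), "nope")
})

test_that("the largest change entries sit inside the planted block", {
  tab <- toy_rewired(3, n_per_group = 200)
  ch <- adjacency_change(tab, "a", "b")
  block <- c("m01", "m02", "m03")
  C <- ch$C
  in_block <- C[block, block][upper.tri(diag(3))]
  out_block <- C[!rownames(C) %in% block, !colnames(C) %in% block]
  out_block <- out_block[upper.tri(out_block)]
  expect_gt(min(in_block), max(out_block))
})

test_that("zero-variance analytes are excluded and listed", {
  tab <- toy_rewired(4, n_per_group = 30)
  tab$X[, "m09"] <- 5
  ch <- adjacency_change(tab, "a", "b")
  expect_equal(ch$excluded, "m09")
  expect_false("m09" %in% ch$analytes)
})

test_that("mean silhouette agrees with the brute-force definition", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- cluster::silhouette(labels, dmatrix = D)
    expect_equal(mean(got[, "sil_width"]), silhouette_oracle(labels, D),
                 tolerance = 1e-12)
  }
})

test_that("silhouette-guided Ward recovers planted rewiring partitions", {
  two_blocks <- list(list(codes = c("m01", "m02", "m03", "m04"), rho = 0.8),
                     list(codes = c("m05", "m06", "m07", "m08"), rho = 0.8))
  recovered <- vapply(1:20, function(s) {
    tab <- toy_rewired(s, n_per_group = 200, n_analytes = 8,
                       blocks_b = two_blocks)
    cl <- ward_silhouette(adjacency_change(tab, "a", "b"))
    cl$k == 2 &&
      length(unique(cl$labels[c("m01", "m02", "m03", "m04")])) == 1 &&
      length(unique(cl$labels[c("m05", "m06", "m07", "m08")])) == 1
  }, NA)
  expect_gte(sum(recovered), 18)

  three_blocks <- list(list(codes = c("m01", "m02", "m03"), rho = 0.8),
                       list(codes = c("m04", "m05", "m06"), rho = 0.8),
                       list(codes = c("m07", "m08", "m09"), rho = 0.8))
  k3 <- vapply(1:10, function(s) {
    tab <- toy_rewired(100 + s, n_per_group = 200, n_analytes = 9,
                       blocks_b = three_blocks)
    ward_silhouette(adjacency_change(tab, "a", "b"))$k
  }, 0L)
  expect_gte(sum(k3 == 3), 8)
})

test_that("a singleton k_range is honoured regardless of silhouette", {
  tab <- toy_rewired(5, n_per_group = 50)
  cl <- ward_silhouette(adjacency_change(tab, "a", "b"), k_range = 2)
  expect_equal(cl$k, 2L)
  expect_error(ward_silhouette(adjacency_change(tab, "a", "b"),
                               k_range = c(1, 2)), "k_range")
})

test_that("clustering is invariant to analyte input order", {
  tab <- toy_rewired(6, n_per_group = 200, n_analytes = 8,
                     blocks_b = list(list(codes = c("m01", "m02", "m03", "m04"),
                                          rho = 0.8),
                                     list(codes = c("m05", "m06", "m07", "m08"),
                                          rho = 0.8)))
  cl1 <- ward_silhouette(adjacency_change(tab, "a", "b"))
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  tab2 <- tab
  tab2$X <- tab$X[, perm]
  tab2$panel <- tab$panel[perm, ]
  class(tab2$panel) <- class(tab$panel)
  cl2 <- ward_silhouette(adjacency_change(tab2, "a", "b"))
  expect_equal(cl1$k, cl2$k)
  common <- names(cl1$labels)
  agree <- table(cl1$labels[common], cl2$labels[common])
  expect_equal(sum(agree > 0), cl1$k)  # one-to-one label correspondence
})

test_that("the inflammation scenario's rewired compounds split in two", {
  sc <- scenario_library()$lps_vs_lps_hie
  tpl <- sc$template
  for (i in seq_along(tpl$groups)) tpl$groups[[i]]$n <- 150
  tab <- generate_cohort(tpl, sc$noise, seed = 9)
  aa_block <- c("glycine", "alanine", "methionine", "valine",
                "phenylalanine", "tyrosine")
  sc_block <- c("C4", "C5", "C5DC/C6OH", "C8:1", "C6", "C8")
  sub <- tab
  keep <- c(aa_block, sc_block)
  sub$X <- tab$X[, keep]
  sub$panel <- tab$panel[match(keep, tab$panel$code), ]
  class(sub$panel) <- class(tab$panel)
  cl <- ward_silhouette(adjacency_change(sub, "lps", "lps_hie"))
  expect_equal(cl$k, 2L)
  expect_equal(length(unique(cl$labels[aa_block])), 1L)
  expect_equal(length(unique(cl$labels[sc_block])), 1L)
})
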