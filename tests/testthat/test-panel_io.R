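test_that("default panel matches the assay's class composition", {
  p <- default_panel()
  expect_s3_class(p, "metabolite_panel")
  expect_equal(nrow(p), 57)
  counts <- table(p$class)
  expect_equal(counts[["amino_acid"]], 14)
  expect_equal(counts[["acylcarnitine"]], 36)
  expect_equal(counts[["nucleoside"]], 2)
  expect_equal(counts[["succinylacetone"]], 1)
  expect_equal(counts[["lysophosphatidylcholine"]], 4)
  expect_false(anyDuplicated(p$code) > 0)
  expect_true(all(lengths(p$variants) >= 1))
  ambiguous <- grepl("/", p$code, fixed = TRUE)
  expect_true(all(lengths(p$variants)[ambiguous] >= 2))
})

test_that("every analyte documented in the study narrative is present", {
  codes <- default_panel()$code
  named <- c("glycine", "methionine", "alanine", "valine", "ornithine",
             "citrulline", "phenylalanine", "tyrosine", "glutamate",
             "arginine", "argininosuccinate", "Leu/Ile/Hyp", "Gln/Lys",
             "succinylacetone", "deoxyadenosine",
             "C2", "C3", "C3DC/C4OH", "C4", "C5", "C5:1", "C5DC/C6OH",
             "C6", "C8", "C8:1", "C10:2", "C14", "C14:1", "C14:2", "C18",
             "C18:2", "C20", "C24", "C26",
             "LPC C20:0", "LPC C22:0", "LPC C24:0", "LPC C26:0")
  expect_true(all(named %in% codes))
})

test_that("identification variants resolve combined codes", {
  p <- default_panel()
  expect_setequal(panel_variants(p, "Gln/Lys"), c("glutamine", "lysine"))
  expect_setequal(panel_variants(p, "C3DC/C4OH"),
                  c("malonylcarnitine", "3-hydroxybutyrylcarnitine"))
  expect_setequal(panel_variants(p, "Leu/Ile/Hyp"),
                  c("leucine", "isoleucine", "hydroxyproline"))
  expect_equal(panel_variants(p, "glycine"), "glycine")
  expect_error(panel_variants(p, "C99"), "unknown analyte")
})

test_that("panel constructor enforces its invariants", {
  expect_error(metabolite_panel(c("a", "a"), rep("amino_acid", 2),
                                list("x", "y")), "duplicate")
  expect_error(metabolite_panel("a", "not_a_class", list("x")),
               "unknown analyte class")
  expect_error(metabolite_panel("a/b", "amino_acid", list("x")),
               "ambiguous code")
})

test_that("sample tables round-trip through CSV and TSV losslessly", {
  tab <- planted_cohort(1, panel = small_panel(), n_a = 3, n_b = 3)
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_sample_table(tab, path)
    back <- read_sample_table(path, panel = small_panel())
    expect_equal(back$X, tab$X, tolerance = 1e-10)
    expect_equal(back$meta$group, tab$meta$group)
    expect_equal(back$meta$time_h, tab$meta$time_h)
  }
})

test_that("reader validates columns, concentrations and metadata", {
  tab <- planted_cohort(1, panel = small_panel(), n_a = 3, n_b = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tab, path)
  df <- read.csv(path, check.names = FALSE)

  df_bad <- df; df_bad$C99 <- 1
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df_bad, p1, row.names = FALSE)
  expect_error(read_sample_table(p1, small_panel()), "unknown analyte")

  df_neg <- df; df_neg$glycine[2] <- -1
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df_neg, p2, row.names = FALSE)
  expect_error(read_sample_table(p2, small_panel()), "negative concentration")

  df_nog <- df; df_nog$group[1] <- NA
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df_nog, p3, row.names = FALSE)
  expect_error(read_sample_table(p3, small_panel()), "group")
})

test_that("experimental group sizes survive the round trip", {
  sc <- scenario_library()
  tab <- generate_cohort(sc$hie_timecourse$template, sc$hie_timecourse$noise,
                         seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tab, path)
  back <- read_sample_table(path)
  expect_equal(as.vector(group_sizes(back)[c("control", "hie3h", "hie6h")]),
               c(10L, 13L, 12L))
})

test_that("GMT parsing builds pathway sets and flags malformed input", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tglycine\talanine\tserine",
               "pw2\tdesc\tglycine\tlysine\tcarnitine\tmethionine"), path)
  ps <- read_gmt(path, library_tag = "SMPDB")
  expect_equal(length(ps$pathways), 2L)
  expect_lte(length(ps$universe), 7L)
  expect_true("glycine" %in% ps$pathways$pw1)
  expect_true("glycine" %in% ps$universe)

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_error(read_gmt(empty), "no pathways")

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tglycine", "broken\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("restricting the GMT universe intersects the pathways", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tglycine\talanine\tserine"), path)
  ps <- read_gmt(path, universe = c("glycine", "alanine", "methionine"))
  expect_setequal(ps$pathways$pw1, c("glycine", "alanine"))
  expect_false("serine" %in% ps$universe)
})

test_that("pipeline configuration is validated", {
  expect_error(pipeline_config(alpha_univariate = 1.5), "alpha")
  expect_error(pipeline_config(alpha_enrichment = 0), "alpha")
  expect_error(pipeline_config(seed = -1), "seed")
  expect_error(pipeline_config(seed = 1.5), "seed")
  cfg <- pipeline_config(seed = 7)
  expect_s3_class(cfg, "pipeline_config")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: hie_timecourse", "seed: 7",
               "alpha_univariate: 0.01"), yml)
  cfg2 <- config_from_yaml(yml)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$alpha_univariate, 0.01)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(config_from_yaml(bad), "unknown config key")
})
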