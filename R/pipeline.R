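#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the input table (a file path
#' or a built-in simulation scenario), the groups to contrast, tuning
#' parameters and the output directory.
#'
#' @param input Path to a concentration CSV/TSV, or `NULL` to simulate.
#' @param scenario Name of a [scenario_library()] scenario (used when
#'   `input` is `NULL`; default `"hie_timecourse"`).
#' @param group_control,group_case Group labels for the two-class stages
#'   (network, enrichment markers, OPLS-DA, logistic model).
#' @param gmt Path to a GMT pathway file; default is the small synthetic
#'   compound-pathway collection shipped with the package.
#' @param universe `"panel"` (restrict the pathway universe to the panel's
#'   compound variants, default) or `"library"` (union of all pathway
#'   members).
#' @param alpha_univariate Significance level for the univariate stage
#'   (default 0.05).
#' @param alpha_enrichment Per-set ORA significance level (default 0.1).
#' @param n_orthogonal Orthogonal components for the OPLS-DA stages
#'   (default 2).
#' @param seed Nonnegative integer RNG seed.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, scenario = "hie_timecourse",
                            group_control = "control", group_case = "hie6h",
                            gmt = NULL, universe = c("panel", "library"),
                            alpha_univariate = 0.05, alpha_enrichment = 0.1,
                            n_orthogonal = 2, seed = 1, out_dir = NULL) {
  universe <- match.arg(universe)
  for (a in c(alpha_univariate, alpha_enrichment)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(seed) || seed < 0 || seed != round(seed)) {
    stop("seed must be a nonnegative integer")
  }
  if (is.null(gmt)) {
    gmt <- system.file("extdata", "example_pathways_synthetic.gmt",
                       package = "neodx")
  }
  structure(list(input = input, scenario = scenario,
                 group_control = group_control, group_case = group_case,
                 gmt = gmt, universe = universe,
                 alpha_univariate = alpha_univariate,
                 alpha_enrichment = alpha_enrichment,
                 n_orthogonal = n_orthogonal, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys mirror the
#'   `pipeline_config()` arguments.
#' @export
config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  do.call(pipeline_config, args)
}

run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %s: done", name))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — univariate screening (all pairwise group
#' comparisons, plus Spearman time association when sampling times are
#' present), PCA on the significant compounds, differential correlation
#' network clustering, consensus pathway over-representation of the
#' case-vs-control markers, OPLS-DA with LOO cross-validation, and the
#' stepwise logistic diagnostic model — and writes per-stage CSV files,
#' a JSON metrics summary and a log to `out_dir`. Identical configuration
#' and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param table Optional [sample_table()] overriding `config$input` /
#'   `config$scenario`.
#' @return List of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  log_lines <- character(0)
  log <- function(msg) {
    log_lines[[length(log_lines) + 1]] <<- sprintf("[%s] %s", "neodx", msg)
    invisible(NULL)
  }
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if (is.null(table)) {
    table <- run_stage("input", log, {
      if (!is.null(config$input)) {
        read_sample_table(config$input)
      } else {
        sc <- scenario_library()[[config$scenario]]
        if (is.null(sc)) stop("unknown scenario: ", config$scenario)
        generate_cohort(sc$template, sc$noise, seed = config$seed)
      }
    })
  }
  groups <- unique(table$meta$group)
  for (g in c(config$group_control, config$group_case)) {
    if (!g %in% groups) stop("configured group not in table: ", g)
  }

  univariate <- run_stage("univariate", log, {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    comp <- do.call(rbind, lapply(pairs, function(pr) {
      compare_groups(table, pr[1], pr[2], alpha = config$alpha_univariate)
    }))
    times <- NULL
    if (length(unique(stats::na.omit(table$meta$time_h))) >= 2) {
      times <- spearman_time(table, alpha = config$alpha_univariate)
      emit(times, "time_association.csv")
    }
    emit(comp, "univariate.csv")
    list(comparisons = comp, time_association = times)
  })

  pca <- run_stage("pca", log, {
    comp <- univariate$comparisons
    sel <- unique(comp$analyte[comp$significant_raw])
    if (length(sel) < 2) {
      log("pca: fewer than 2 significant analytes; skipped")
      NULL
    } else {
      res <- pca_on_significant(table, sel)
      emit(data.frame(sample_id = rownames(res$scores),
                      group = table$meta$group, res$scores[, 1:2]),
           "pca_scores.csv")
      res
    }
  })

  network <- run_stage("network", log, {
    ch <- adjacency_change(table, config$group_control, config$group_case)
    if (ch$no_rewiring) {
      list(change = ch, clusters = NULL)
    } else {
      cl <- ward_silhouette(ch)
      emit(data.frame(analyte = names(cl$labels), cluster = cl$labels),
           "network_clusters.csv")
      list(change = ch, clusters = cl)
    }
  })

  enrichment <- run_stage("enrichment", log, {
    comp <- univariate$comparisons
    case_cmp <- comp[comp$comparison ==
                       paste(config$group_control, "vs", config$group_case), ]
    markers <- case_cmp$analyte[case_cmp$significant_raw]
    if (!length(markers)) {
      log("enrichment: no significant markers; skipped")
      NULL
    } else {
      uni <- if (config$universe == "panel") panel_universe(table$panel) else NULL
      ps <- read_gmt(config$gmt, universe = uni)
      fam <- expand_markers(markers, table$panel)
      res <- consensus_enrich(fam, ps, alpha = config$alpha_enrichment)
      emit(res, "enrichment.csv")
      res
    }
  })

  sub <- subset_groups(table, c(config$group_control, config$group_case))
  y <- as.numeric(sub$meta$group == config$group_case)

  opls <- run_stage("opls", log, {
    fit <- fit_opls(sub$X, y, n_ortho = config$n_orthogonal)
    cv <- loo_cv_opls(sub$X, y, n_ortho = config$n_orthogonal)
    ok <- !is.na(cv$cv_scores)
    yj <- youden_cutoff(cv$cv_scores[ok], y[ok])
    rc <- roc(cv$cv_scores[ok], y[ok])
    emit(data.frame(sample_id = sub$meta$sample_id, group = sub$meta$group,
                    t_pred = fit$t,
                    t_ortho1 = if (config$n_orthogonal > 0) fit$T_o[, 1] else NA),
         "opls_scores.csv")
    list(model = fit, Q2 = cv$Q2, cv_scores = cv$cv_scores, roc = rc,
         cutoff = yj$cutoff, sensitivity = yj$sensitivity,
         specificity = yj$specificity,
         vip = sort(fit$VIP, decreasing = TRUE))
  })

  logistic <- run_stage("logistic", log, {
    features <- expand_features(sub)
    model <- build_dx_model(features, y, n_ortho = config$n_orthogonal)
    cv <- loo_cv_logit(features, y, n_ortho = config$n_orthogonal)
    list(model = model, cv = cv)
  })

  summary <- list(
    seed = config$seed,
    groups = list(control = config$group_control, case = config$group_case),
    univariate = list(
      n_significant_raw = sum(univariate$comparisons$significant_raw),
      n_significant_fdr = sum(univariate$comparisons$significant)),
    opls = list(R2X = opls$model$R2X, R2Y = opls$model$R2Y, Q2 = opls$Q2,
                auc = opls$roc$auc, cutoff = opls$cutoff,
                sensitivity = opls$sensitivity,
                specificity = opls$specificity,
                vip_gt1 = names(opls$vip)[opls$vip > 1]),
    logistic = list(features = logistic$model$features,
                    auc = logistic$cv$auc, cutoff = logistic$cv$cutoff,
                    sensitivity = logistic$cv$sensitivity,
                    specificity = logistic$cv$specificity))
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  structure(list(table = table, univariate = univariate, pca = pca,
                 network = network, enrichment = enrichment, opls = opls,
                 logistic = logistic, summary = summary, log = log_lines),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  univariate: %d raw-significant, %d FDR-significant tests\n",
              s$univariate$n_significant_raw, s$univariate$n_significant_fdr))
  cat(sprintf("  OPLS-DA: R2X=%.2f R2Y=%.2f Q2=%.2f AUC=%.2f sens=%.2f spec=%.2f\n",
              s$opls$R2X, s$opls$R2Y, s$opls$Q2, s$opls$auc,
              s$opls$sensitivity, s$opls$specificity))
  cat(sprintf("  logistic: [%s] AUC=%.2f sens=%.2f spec=%.2f\n",
              paste(s$logistic$features, collapse = ", "),
              s$logistic$auc, s$logistic$sensitivity, s$logistic$specificity))
  invisible(x)
}
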