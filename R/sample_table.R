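#' Sample-by-analyte concentration table
#'
#' Container for a dried-blood-spot screening dataset: a numeric matrix of
#' concentrations (micromol/L, one row per sample, one column per panel
#' analyte) plus per-sample metadata. Metadata carry a mandatory group label,
#' an optional sampling time in hours post-insult (`time_h`, `NA` when not
#' applicable) and a treatment tag.
#'
#' @param X Numeric matrix, samples x analytes, nonnegative and finite;
#'   column names must match the panel codes.
#' @param meta Data frame with columns `sample_id`, `group`, and optionally
#'   `time_h` and `treatment`; one row per row of `X`.
#' @param panel A [metabolite_panel()].
#' @return An object of class `sample_table` with elements `X`, `meta`,
#'   `panel`.
#' @export
sample_table <- function(X, meta, panel = default_panel()) {
  stopifnot(inherits(panel, "metabolite_panel"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("X must carry analyte codes as column names")
  if (!setequal(colnames(X), panel$code)) {
    unknown <- setdiff(colnames(X), panel$code)
    if (length(unknown)) stop("unknown analyte column: ", unknown[1])
    stop("missing analyte column: ", setdiff(panel$code, colnames(X))[1])
  }
  X <- X[, panel$code, drop = FALSE]   # normalize to panel order
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("meta must have sample_id and group columns")
  }
  if (nrow(meta) != nrow(X)) stop("meta rows must match X rows")
  if (anyNA(meta$group) || any(!nzchar(as.character(meta$group)))) {
    stop("missing group label for sample ",
         meta$sample_id[which(is.na(meta$group) | !nzchar(as.character(meta$group)))[1]])
  }
  if (is.null(meta$time_h)) meta$time_h <- NA_real_
  meta$time_h <- as.numeric(meta$time_h)
  if (is.null(meta$treatment)) meta$treatment <- "none"
  treatments <- c("none", "LPS", "LPS+HIE", "HIE", "HIE+TH")
  badt <- setdiff(unique(meta$treatment), treatments)
  if (length(badt)) stop("unknown treatment: ", badt[1])
  if (anyNA(X) || any(!is.finite(X))) {
    ij <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite concentration at sample %s, analyte %s",
                 meta$sample_id[ij[1]], colnames(X)[ij[2]]))
  }
  if (any(X < 0)) {
    ij <- which(X < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative concentration at sample %s, analyte %s",
                 meta$sample_id[ij[1]], colnames(X)[ij[2]]))
  }
  rownames(X) <- meta$sample_id
  structure(list(X = X, meta = meta, panel = panel), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d analytes\n",
              nrow(x$X), ncol(x$X)))
  print(table(x$meta$group))
  invisible(x)
}

#' @rdname sample_table
#' @param table A `sample_table`.
#' @param groups Character vector of group labels to keep.
#' @return `subset_groups()` returns a `sample_table` restricted to the
#'   requested groups.
#' @export
subset_groups <- function(table, groups) {
  stopifnot(inherits(table, "sample_table"))
  missing <- setdiff(groups, unique(table$meta$group))
  if (length(missing)) stop("group absent from table: ", missing[1])
  keep <- table$meta$group %in% groups
  sample_table(table$X[keep, , drop = FALSE],
               table$meta[keep, , drop = FALSE], table$panel)
}

#' Group sizes of a sample table
#' @param table A [sample_table()].
#' @return Named integer vector of samples per group.
#' @export
group_sizes <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  table(table$meta$group)
}
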