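#' Read a concentration table from CSV/TSV
#'
#' The file must have a header row with the metadata columns `sample_id` and
#' `group` (optionally `time_h`, `treatment`) and one column per panel
#' analyte code. Field separator is sniffed from the extension (`.tsv` ->
#' tab, otherwise comma). Analyte columns are reordered to the panel order.
#'
#' @param path Path to a CSV or TSV file (UTF-8, decimal point).
#' @param panel A [metabolite_panel()]; defaults to [default_panel()].
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, panel = default_panel()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  meta_cols <- intersect(c("sample_id", "group", "time_h", "treatment"), names(df))
  analyte_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(analyte_cols, panel$code)
  if (length(unknown)) stop("unknown analyte column: ", unknown[1])
  X <- as.matrix(df[, analyte_cols, drop = FALSE])
  sample_table(X, df[, meta_cols, drop = FALSE], panel)
}

#' Write a concentration table to CSV/TSV
#'
#' Inverse of [read_sample_table()]: metadata columns first, then analyte
#' columns in panel order. Round-trips losslessly at full double precision.
#'
#' @param table A [sample_table()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- cbind(table$meta[c("sample_id", "group", "time_h", "treatment")],
              as.data.frame(table$X, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read compound pathway sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name <tab> description <tab> member...`. The universe defaults to the
#' union of all members; pass `universe` to override (e.g. to restrict to
#' the panel's compound variants).
#'
#' @param path Path to a GMT file.
#' @param library_tag Label for the source library (e.g. `"SMPDB"`).
#' @param universe Optional character vector overriding the compound
#'   universe; every pathway is intersected with it.
#' @return A `pathway_set`: list with `name`, `library`, `pathways` (named
#'   list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, library_tag = "custom", universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no pathways in GMT file: ", path)
  pathways <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    pathways[[fields[[1]]]] <- members
  }
  pathway_set(name = basename(path), library_tag = library_tag,
              pathways = pathways, universe = universe)
}

#' @rdname read_gmt
#' @param name Name for the collection.
#' @param pathways Named list of character vectors (pathway -> members).
#' @export
pathway_set <- function(name, library_tag, pathways, universe = NULL) {
  if (!length(pathways)) stop("no pathways")
  if (is.null(names(pathways)) || any(!nzchar(names(pathways)))) {
    stop("pathways must be named")
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathways, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    pathways <- lapply(pathways, intersect, y = universe)
    pathways <- pathways[lengths(pathways) > 0]
    if (!length(pathways)) stop("no pathways overlap the supplied universe")
  }
  structure(list(name = name, library = library_tag,
                 pathways = pathways, universe = universe),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("<pathway_set> %s [%s]: %d pathways, universe %d compounds\n",
              x$name, x$library, length(x$pathways), length(x$universe)))
  invisible(x)
}
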