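#' Metabolite panel definitions
#'
#' A `metabolite_panel` describes the analyte catalogue of a targeted
#' newborn-screening assay: one row per measured analyte, with the code as
#' printed by the assay software, the compound class, and the unambiguous
#' compound name(s) the code may denote. Combined (isobaric) codes such as
#' `"Gln/Lys"` carry several identification variants; they are treated as a
#' single measured variable by all statistics and only expanded into their
#' variants for pathway over-representation analysis (see
#' [expand_markers()]).
#'
#' @param code Character vector of analyte codes (unique, nonempty).
#' @param class Character vector of compound classes; one of
#'   `"amino_acid"`, `"acylcarnitine"`, `"nucleoside"`, `"succinylacetone"`,
#'   `"lysophosphatidylcholine"`.
#' @param variants List of character vectors: for each code, the unambiguous
#'   compound names it may denote (length >= 1; codes containing `/` must
#'   have >= 2 variants).
#' @param placeholder Logical vector: `TRUE` marks catalogue slots filled in
#'   to reach the assay's class composition where the exact analyte identity
#'   is not pinned down by the study narrative (see [default_panel()]).
#'
#' @return An object of class `metabolite_panel`: a data frame with columns
#'   `code`, `class`, `variants` (list column) and `placeholder`.
#' @seealso [default_panel()], [panel_variants()]
#' @export
metabolite_panel <- function(code, class, variants, placeholder = FALSE) {
  code <- as.character(code)
  class <- as.character(class)
  stopifnot(length(code) == length(class), length(code) == length(variants))
  placeholder <- rep_len(as.logical(placeholder), length(code))
  classes <- c("amino_acid", "acylcarnitine", "nucleoside",
               "succinylacetone", "lysophosphatidylcholine")
  if (anyDuplicated(code)) {
    stop("duplicate analyte code: ", code[duplicated(code)][1])
  }
  bad <- setdiff(unique(class), classes)
  if (length(bad)) stop("unknown analyte class: ", bad[1])
  variants <- lapply(variants, as.character)
  nvar <- lengths(variants)
  if (any(nvar < 1)) stop("every analyte needs at least one variant")
  ambiguous <- grepl("/", code, fixed = TRUE)
  if (any(ambiguous & nvar < 2)) {
    stop("ambiguous code with a single variant: ", code[ambiguous & nvar < 2][1])
  }
  out <- data.frame(code = code, class = class, placeholder = placeholder,
                    stringsAsFactors = FALSE)
  out$variants <- variants
  structure(out[, c("code", "class", "variants", "placeholder")],
            class = c("metabolite_panel", "data.frame"))
}

# carnitine ester name for a chain code, used for the built-in catalogue
.acyl <- function(code, name) list(code = code, name = name)

#' Built-in 57-analyte dried-blood-spot screening panel
#'
#' Returns the default analyte catalogue modelled on a non-derivatized
#' tandem-MS newborn screening panel quantifying 57 low-molecular-weight
#' compounds: 14 amino acids, 36 acylcarnitines, 2 nucleosides,
#' succinylacetone, and 4 lysophosphatidylcholines. Every analyte with a
#' documented role in the hypoxia-ischemia analyses is present under its
#' printed code (e.g. `"glycine"`, `"methionine"`, `"C3DC/C4OH"`,
#' `"Gln/Lys"`, `"Leu/Ile/Hyp"`); the remaining catalogue slots are filled
#' with standard screening-panel codes and flagged `placeholder = TRUE`,
#' since the full assay sheet is not restated here. The panel can be
#' overridden by constructing a [metabolite_panel()] from a user file.
#'
#' @return A [metabolite_panel()] with exactly 57 analytes.
#' @examples
#' p <- default_panel()
#' table(p$class)
#' panel_variants(p, "Gln/Lys")
#' @export
default_panel <- function() {
  aa <- list(
    list("alanine",       "alanine",                FALSE),
    list("arginine",      "arginine",               FALSE),
    list("argininosuccinate", "argininosuccinic acid", FALSE),
    list("citrulline",    "citrulline",             FALSE),
    list("glutamate",     "glutamate",              FALSE),
    list("Gln/Lys",       c("glutamine", "lysine"), FALSE),
    list("glycine",       "glycine",                FALSE),
    list("Leu/Ile/Hyp",   c("leucine", "isoleucine", "hydroxyproline"), FALSE),
    list("methionine",    "methionine",             FALSE),
    list("ornithine",     "ornithine",              FALSE),
    list("phenylalanine", "phenylalanine",          FALSE),
    list("proline",       "proline",                TRUE),
    list("tyrosine",      "tyrosine",               FALSE),
    list("valine",        "valine",                 FALSE)
  )
  ac <- list(
    list("C0",        "carnitine",                    TRUE),
    list("C2",        "acetylcarnitine",              FALSE),
    list("C3",        "propionylcarnitine",           FALSE),
    list("C3DC/C4OH", c("malonylcarnitine", "3-hydroxybutyrylcarnitine"), FALSE),
    list("C4",        "butyrylcarnitine",             FALSE),
    list("C4DC/C5OH", c("methylmalonylcarnitine", "3-hydroxyisovalerylcarnitine"), TRUE),
    list("C5",        "valerylcarnitine",             FALSE),
    list("C5:1",      "tiglylcarnitine",              FALSE),
    list("C5DC/C6OH", c("glutarylcarnitine", "3-hydroxyhexanoylcarnitine"), FALSE),
    list("C6",        "hexanoylcarnitine",            FALSE),
    list("C6DC",      "adipylcarnitine",              TRUE),
    list("C8",        "octanoylcarnitine",            FALSE),
    list("C8:1",      "2-octenoylcarnitine",          FALSE),
    list("C10",       "decanoylcarnitine",            TRUE),
    list("C10:1",     "decenoylcarnitine",            TRUE),
    list("C10:2",     "decadienoylcarnitine",         FALSE),
    list("C12",       "dodecanoylcarnitine",          TRUE),
    list("C12:1",     "dodecenoylcarnitine",          TRUE),
    list("C14",       "tetradecanoylcarnitine",       FALSE),
    list("C14:1",     "tetradecenoylcarnitine",       FALSE),
    list("C14:2",     "tetradecadienoylcarnitine",    FALSE),
    list("C14OH",     "3-hydroxytetradecanoylcarnitine", TRUE),
    list("C16",       "palmitoylcarnitine",           TRUE),
    list("C16:1",     "palmitoleylcarnitine",         TRUE),
    list("C16OH",     "3-hydroxypalmitoylcarnitine",  TRUE),
    list("C16:1OH",   "3-hydroxypalmitoleylcarnitine", TRUE),
    list("C18",       "octadecanoylcarnitine",        FALSE),
    list("C18:1",     "oleoylcarnitine",              TRUE),
    list("C18:2",     "octadecadienoylcarnitine",     FALSE),
    list("C18OH",     "3-hydroxystearoylcarnitine",   TRUE),
    list("C18:1OH",   "3-hydroxyoleoylcarnitine",     TRUE),
    list("C18:2OH",   "3-hydroxylinoleoylcarnitine",  TRUE),
    list("C20",       "arachidoylcarnitine",          FALSE),
    list("C22",       "docosanoylcarnitine",          TRUE),
    list("C24",       "lignoceroylcarnitine",         FALSE),
    list("C26",       "hexacosanoylcarnitine",        FALSE)
  )
  nuc <- list(
    list("adenosine",      "adenosine",      TRUE),
    list("deoxyadenosine", "deoxyadenosine", FALSE)
  )
  sa <- list(list("succinylacetone", "succinylacetone", FALSE))
  lpc <- list(
    list("LPC C20:0", "lysophosphatidylcholine C20:0", FALSE),
    list("LPC C22:0", "lysophosphatidylcholine C22:0", FALSE),
    list("LPC C24:0", "lysophosphatidylcholine C24:0", FALSE),
    list("LPC C26:0", "lysophosphatidylcholine C26:0", FALSE)
  )
  defs <- c(aa, ac, nuc, sa, lpc)
  cls <- rep(c("amino_acid", "acylcarnitine", "nucleoside",
               "succinylacetone", "lysophosphatidylcholine"),
             times = c(length(aa), length(ac), length(nuc),
                       length(sa), length(lpc)))
  metabolite_panel(
    code = vapply(defs, function(d) d[[1]], ""),
    class = cls,
    variants = lapply(defs, function(d) d[[2]]),
    placeholder = vapply(defs, function(d) d[[3]], NA)
  )
}

#' Identification variants of a panel code
#'
#' @param panel A [metabolite_panel()].
#' @param code A single analyte code.
#' @return Character vector of unambiguous compound names.
#' @export
panel_variants <- function(panel, code) {
  stopifnot(inherits(panel, "metabolite_panel"), length(code) == 1L)
  i <- match(code, panel$code)
  if (is.na(i)) stop("unknown analyte code: ", code)
  panel$variants[[i]]
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("<metabolite_panel> %d analytes\n", nrow(x)))
  print(table(x$class))
  amb <- x$code[vapply(x$variants, length, 0L) > 1]
  if (length(amb)) cat("ambiguous codes:", paste(amb, collapse = ", "), "\n")
  invisible(x)
}
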