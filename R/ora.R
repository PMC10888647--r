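#' Expand ambiguous marker codes into compound name sets
#'
#' Isobaric panel codes (e.g. `"Gln/Lys"`) denote several possible
#' compounds. For over-representation analysis, one marker name-set is
#' created per combination of identification variants (Cartesian product
#' over the ambiguous codes), each set containing exactly one name per
#' marker.
#'
#' @param codes Character vector of panel codes (the marker list).
#' @param panel A [metabolite_panel()].
#' @return List of class `marker_set_family`: `codes`, `sets` (list of
#'   character vectors, one per variant combination).
#' @export
expand_markers <- function(codes, panel = default_panel()) {
  if (!length(codes)) stop("empty marker list")
  unknown <- setdiff(codes, panel$code)
  if (length(unknown)) stop("unknown analyte code: ", unknown[1])
  variant_lists <- lapply(codes, panel_variants, panel = panel)
  grid <- expand.grid(rev(variant_lists), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  sets <- lapply(seq_len(nrow(grid)), function(i) {
    unname(rev(unlist(grid[i, ], use.names = FALSE)))
  })
  structure(list(codes = codes, sets = sets), class = "marker_set_family")
}

#' Hypergeometric over-representation test
#'
#' One-sided enrichment of a marker name-set in a pathway compound set:
#' `p = P(X >= hits)` for `X` hypergeometric with population `|universe|`,
#' `|pathway|` successes and `|markers %in% universe|` draws. The
#' enrichment ratio is observed over expected hits.
#'
#' @param markers Character vector of compound names; the effective list is
#'   its intersection with the universe.
#' @param pathway Character vector of compound names (subset of universe).
#' @param universe Character vector: the compound universe.
#' @return List with `p`, `enrichment_ratio`, `hits`, `n_markers` (effective),
#'   `pathway_size`, `universe_size`.
#' @export
ora <- function(markers, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(pathway, universe))) {
    stop("pathway contains compounds outside the universe")
  }
  markers <- unique(intersect(markers, universe))
  if (!length(markers)) stop("no markers in universe (empty effective list)")
  pathway <- unique(pathway)
  hits <- length(intersect(markers, pathway))
  N <- length(universe)
  K <- length(pathway)
  n <- length(markers)
  p <- stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  list(p = p, enrichment_ratio = hits / expected, hits = hits,
       n_markers = n, pathway_size = K, universe_size = N)
}

#' Consensus enrichment across identification-variant marker sets
#'
#' Runs [ora()] for every expanded marker set of a [expand_markers()] family
#' against every pathway. A pathway is consensus-significant only when its
#' enrichment p is below `alpha` for *every* marker set; p and enrichment
#' ratio are averaged across sets and the hit count is summarized by its
#' median. Marker sets with no compound in the universe contribute `p = 1`,
#' enrichment 0 and 0 hits (a variant combination entirely outside the
#' library cannot support enrichment). No multiplicity correction is
#' applied across pathways.
#'
#' @param family A `marker_set_family` from [expand_markers()].
#' @param pathway_set A [pathway_set()].
#' @param alpha Per-set significance level (default 0.1).
#' @return Data frame of class `enrichment_result`, one row per pathway:
#'   `pathway`, `library`, `consensus_significant`, `mean_p`,
#'   `mean_enrichment`, `median_hits`, `max_p`, `n_sets`.
#' @export
consensus_enrich <- function(family, pathway_set, alpha = 0.1) {
  stopifnot(inherits(family, "marker_set_family"),
            inherits(pathway_set, "pathway_set"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  universe <- pathway_set$universe
  rows <- lapply(names(pathway_set$pathways), function(pw) {
    res <- lapply(family$sets, function(markers) {
      if (!length(intersect(markers, universe))) {
        return(list(p = 1, enrichment_ratio = 0, hits = 0))
      }
      ora(markers, pathway_set$pathways[[pw]], universe)
    })
    p <- vapply(res, `[[`, 0, "p")
    er <- vapply(res, `[[`, 0, "enrichment_ratio")
    hits <- vapply(res, `[[`, 0, "hits")
    data.frame(pathway = pw, library = pathway_set$library,
               consensus_significant = all(p < alpha),
               mean_p = mean(p), mean_enrichment = mean(er),
               median_hits = stats::median(hits), max_p = max(p),
               n_sets = length(res), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Compound universe spanned by a panel
#'
#' All identification-variant compound names of a panel, the default ORA
#' universe when the pathway library is consumed panel-relative.
#'
#' @param panel A [metabolite_panel()].
#' @return Character vector of compound names.
#' @export
panel_universe <- function(panel = default_panel()) {
  sort(unique(unlist(panel$variants, use.names = FALSE)))
}
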