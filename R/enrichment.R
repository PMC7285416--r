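#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Validated wrapper around the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): q-values are monotone in the sorted
#' p-values and capped at 1, and the output matches the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  megax_check(is.numeric(p_values) && !anyNA(p_values) &&
                all(p_values >= 0 & p_values <= 1),
              "p-values must be numbers in [0, 1]",
              "megax_validation_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' Hypergeometric upper-tail test of the overlap between a query gene
#' list and each gene set, the over-representation reading of "gene set
#' enrichment" used on fixed gene lists (as opposed to rank-based GSEA).
#' Each set is intersected with the universe before testing; with
#' universe size `N`, set size `K`, query size `n` and overlap `k`,
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Jaccard similarity
#' is `|query ∩ set| / |query ∪ set|`. Rows are sorted by increasing `p`
#' (ties by set name) and BH-FDR q-values are computed over all tested
#' sets.
#'
#' @param query Character vector of query gene symbols (must lie in the
#'   universe).
#' @param collections Gene sets from [read_gene_sets()] (or a list of
#'   lists with `name`, `external_id`, `members`).
#' @param universe Background gene symbols; defaults to the union of all
#'   set members.
#' @return A `data.frame` with columns `set_name`, `set_id`, `set_size`,
#'   `overlap`, `p_value`, `q_value`, `jaccard`.
#' @export
enrich <- function(query, collections, universe = NULL) {
  megax_check(length(collections) > 0L, "no gene sets supplied",
              "megax_validation_error")
  if (is.null(universe))
    universe <- unique(unlist(lapply(collections, `[[`, "members")))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  megax_check(length(universe) > 0L && length(query) > 0L,
              "query and universe must be non-empty",
              "megax_validation_error")
  outside <- setdiff(query, universe)
  megax_check(length(outside) == 0L,
              sprintf("query gene(s) outside the universe: %s",
                      paste(outside, collapse = ", ")),
              "megax_validation_error")
  megax_check(length(universe) >= length(query),
              "universe smaller than query", "megax_validation_error")
  N <- length(universe); n <- length(query)
  rows <- do.call(rbind, lapply(collections, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(
      set_name = s$name, set_id = s$external_id, set_size = K, overlap = k,
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      jaccard = k / length(union(query, members)),
      stringsAsFactors = FALSE)
  }))
  rows$q_value <- bh_fdr(rows$p_value)
  rows <- rows[order(rows$p_value, rows$set_name), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("set_name", "set_id", "set_size", "overlap", "p_value",
           "q_value", "jaccard")]
}
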