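#' @noRd
polarity_map <- function(relations, src = NULL, tgt = NULL, kind) {
  sel <- relations$relation_kind == kind
  if (!is.null(src)) sel <- sel & relations$source == src
  if (!is.null(tgt)) sel <- sel & relations$target == tgt
  rel <- relations[sel, , drop = FALSE]
  key <- if (!is.null(src)) rel$target else rel$source
  dup <- unique(key[duplicated(key)])
  for (g in dup)
    if (length(unique(rel$polarity[key == g])) > 1L)
      megax_stop(sprintf("conflicting polarities for '%s'", g),
                 "megax_validation_error")
  rel <- rel[!duplicated(key), , drop = FALSE]
  list(pol = stats::setNames(rel$polarity,
                             if (!is.null(src)) rel$target else rel$source),
       edges = rel)
}

#' @noRd
mega_sign <- function(mega, gene, eps = 1e-9) {
  if (is.null(mega) || is.null(mega[[gene]])) return(NA_integer_)
  res <- mega[[gene]]
  lfc <- if (inherits(res, "mega_result")) res$pooled_lfc else as.numeric(res)
  if (!is.finite(lfc) || abs(lfc) < eps) return(NA_integer_)
  as.integer(sign(lfc))
}

#' Diagnostic network of contra-directionally regulated genes
#'
#' Intersects the driver's signed regulation edges with the disease's
#' signed association edges and keeps the genes pushed in opposite
#' directions by the two: a *positive marker* is up in the disease
#' (polarity +1) while inhibited by the driver (polarity -1); a *negative
#' marker* is the mirror image. When pooled mega-analysis results are
#' supplied, each marker is additionally labelled `consistent` when the
#' sign of its pooled LFC agrees with the disease polarity,
#' `inconsistent` when it disagrees, and `untested` when no pooled result
#' is available or the pooled LFC is within `1e-9` of zero. Inconsistent
#' genes stay in the network object but are dropped from the default
#' report ([consistent_markers()]).
#'
#' @param relations Signed relation `data.frame`
#'   (see [read_relation_table()]) holding `regulation` edges from
#'   `driver` and `disease_association` edges from `disease`.
#' @param driver Driver entity name (e.g. `"PPARG"`).
#' @param disease Disease entity name (e.g. `"LSCC"`).
#' @param mega Optional named list (per gene) of `mega_result` objects or
#'   pooled LFC numbers used for the consistency labels.
#' @return An object of class `marker_network`: `driver`, `disease`,
#'   `positive_markers`, `negative_markers`, `edges`, `consistency`.
#' @export
build_diagnostic_network <- function(relations, driver, disease,
                                     mega = NULL) {
  drv <- polarity_map(relations, src = driver, kind = "regulation")
  dis <- polarity_map(relations, src = disease, kind = "disease_association")
  genes <- sort(intersect(names(drv$pol), names(dis$pol)))
  positive <- genes[dis$pol[genes] == 1L & drv$pol[genes] == -1L]
  negative <- genes[dis$pol[genes] == -1L & drv$pol[genes] == 1L]
  markers <- c(positive, negative)
  consistency <- vapply(markers, function(g) {
    s <- mega_sign(mega, g)
    if (is.na(s)) "untested"
    else if (s == dis$pol[[g]]) "consistent" else "inconsistent"
  }, character(1L))
  edges <- rbind(drv$edges[drv$edges$target %in% markers, , drop = FALSE],
                 dis$edges[dis$edges$target %in% markers, , drop = FALSE])
  rownames(edges) <- NULL
  structure(list(driver = driver, disease = disease,
                 positive_markers = positive, negative_markers = negative,
                 edges = edges,
                 consistency = consistency),
            class = "marker_network")
}

#' Markers passing the expression-consistency filter
#'
#' The default report of a diagnostic network: marker genes whose pooled
#' expression direction does not contradict the literature-reported
#' disease direction (`consistent` or, when no pooled result was
#' supplied, `untested`).
#'
#' @param network A `marker_network` from [build_diagnostic_network()].
#' @return Character vector of gene symbols.
#' @export
consistent_markers <- function(network) {
  megax_check(inherits(network, "marker_network"),
              "network must be a marker_network", "megax_validation_error")
  m <- c(network$positive_markers, network$negative_markers)
  m[network$consistency[m] != "inconsistent"]
}

#' @export
print.marker_network <- function(x, ...) {
  cat(sprintf("<marker_network> %s vs %s: %d positive + %d negative markers\n",
              x$driver, x$disease, length(x$positive_markers),
              length(x$negative_markers)))
  cat("  positive:", paste(x$positive_markers, collapse = ", "), "\n")
  cat("  negative:", paste(x$negative_markers, collapse = ", "), "\n")
  if (any(x$consistency == "inconsistent"))
    cat("  inconsistent with pooled expression:",
        paste(names(x$consistency)[x$consistency == "inconsistent"],
              collapse = ", "), "\n")
  invisible(x)
}

#' Prognostic chain of driver-regulated disease regulators
#'
#' Assembles driver -> gene -> disease chains: a *promoter* is a gene the
#' driver inhibits (polarity -1) that itself promotes the disease
#' (polarity +1); an *inhibitor* is a gene the driver activates that
#' suppresses the disease. Pooled expression directions, when supplied,
#' are attached as annotation only — unlike the diagnostic network no
#' consistency filter is applied, since upstream regulators may move with
#' the disease rather than against it.
#'
#' @param relations Signed relation `data.frame` holding `regulation`
#'   edges from `driver` and `disease_association` edges from genes into
#'   `disease`.
#' @inheritParams build_diagnostic_network
#' @return An object of class `regulator_chain`: `driver`, `disease`,
#'   `promoters`, `inhibitors`, `edges`, `expression_direction`.
#' @export
build_prognostic_network <- function(relations, driver, disease,
                                     mega = NULL) {
  drv <- polarity_map(relations, src = driver, kind = "regulation")
  dis <- polarity_map(relations, tgt = disease, kind = "disease_association")
  genes <- sort(intersect(names(drv$pol), names(dis$pol)))
  promoters <- genes[drv$pol[genes] == -1L & dis$pol[genes] == 1L]
  inhibitors <- genes[drv$pol[genes] == 1L & dis$pol[genes] == -1L]
  chain <- c(promoters, inhibitors)
  direction <- vapply(chain, function(g) mega_sign(mega, g), integer(1L))
  edges <- rbind(drv$edges[drv$edges$target %in% chain, , drop = FALSE],
                 dis$edges[dis$edges$source %in% chain, , drop = FALSE])
  rownames(edges) <- NULL
  structure(list(driver = driver, disease = disease,
                 promoters = promoters, inhibitors = inhibitors,
                 edges = edges, expression_direction = direction),
            class = "regulator_chain")
}

#' @export
print.regulator_chain <- function(x, ...) {
  cat(sprintf("<regulator_chain> %s -> gene -> %s\n", x$driver, x$disease))
  cat("  disease promoters (driver-inhibited):",
      paste(x$promoters, collapse = ", "), "\n")
  cat("  disease inhibitors (driver-activated):",
      paste(x$inhibitors, collapse = ", "), "\n")
  invisible(x)
}
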