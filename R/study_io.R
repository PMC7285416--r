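#' Study metadata
#'
#' A study-metadata table holds one row per expression study with the
#' columns `study_id`, `n_control`, `n_case`, `country`, `study_age_years`
#' and `organism`. `study_metadata()` validates a single record;
#' [read_study_table()] reads a whole table.
#'
#' @param study_id Accession-like identifier, unique within a collection.
#' @param n_control,n_case Group sample counts (each at least 1).
#' @param country Country of origin of the cohort.
#' @param study_age_years Age of the study in years (non-negative).
#' @param organism Sample organism.
#' @return A one-row `data.frame` with the canonical metadata columns.
#' @export
study_metadata <- function(study_id, n_control, n_case,
                           country = NA_character_,
                           study_age_years = NA_real_,
                           organism = "Homo sapiens") {
  megax_check(is.character(study_id) && length(study_id) == 1L &&
                nzchar(study_id),
              "study_id must be a non-empty string", "megax_validation_error")
  n_control <- as.integer(n_control); n_case <- as.integer(n_case)
  megax_check(!is.na(n_control) && n_control >= 1L &&
                !is.na(n_case) && n_case >= 1L,
              "n_control and n_case must be integers >= 1",
              "megax_validation_error")
  megax_check(is.na(study_age_years) || study_age_years >= 0,
              "study_age_years must be non-negative",
              "megax_validation_error")
  data.frame(study_id = study_id, n_control = n_control, n_case = n_case,
             country = as.character(country),
             study_age_years = as.numeric(study_age_years),
             organism = as.character(organism),
             stringsAsFactors = FALSE)
}

#' @noRd
as_study_metadata <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x)
  megax_check(is.data.frame(x) && nrow(x) == 1L,
              "metadata must be a single study record",
              "megax_validation_error")
  do.call(study_metadata, as.list(x[intersect(
    c("study_id", "n_control", "n_case", "country", "study_age_years",
      "organism"), names(x))]))
}

#' Construct an expression study
#'
#' An `expression_study` bundles a genes-by-samples matrix with per-sample
#' group labels (`"control"`/`"case"`), its study metadata, and the scale
#' of the values (`"linear"` intensities or `"log2"`).
#'
#' @param metadata A one-row metadata record (see [study_metadata()]).
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   gene symbols as rownames. Duplicate symbols (e.g. multiple probes per
#'   gene) are allowed until [collapse_duplicates()] is applied.
#' @param group Character vector of per-sample labels, `"control"` or
#'   `"case"`, one per matrix column.
#' @param scale `"linear"`, `"log2"`, or `NULL` to auto-detect with
#'   [detect_scale()].
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(metadata, values, group, scale = NULL) {
  metadata <- as_study_metadata(metadata)
  megax_check(is.matrix(values) && is.numeric(values) &&
                !is.null(rownames(values)),
              "values must be a numeric matrix with gene-symbol rownames",
              "megax_validation_error")
  megax_check(ncol(values) == length(group),
              sprintf("matrix has %d columns but %d group labels",
                      ncol(values), length(group)),
              "megax_format_error")
  bad <- setdiff(unique(group), c("control", "case"))
  if (length(bad) > 0L)
    megax_stop(sprintf("unknown group label(s): %s",
                       paste(bad, collapse = ", ")),
               "megax_validation_error")
  megax_check(sum(group == "control") == metadata$n_control &&
                sum(group == "case") == metadata$n_case,
              sprintf(
                "group counts (%d control, %d case) disagree with metadata (%d, %d)",
                sum(group == "control"), sum(group == "case"),
                metadata$n_control, metadata$n_case),
              "megax_validation_error")
  study <- structure(
    list(metadata = metadata, genes = rownames(values), values = values,
         group = as.character(group), scale = scale %||% NA_character_),
    class = "expression_study")
  if (is.null(scale)) study$scale <- detect_scale(study)
  else megax_check(scale %in% c("linear", "log2"),
                   "scale must be 'linear' or 'log2'",
                   "megax_validation_error")
  study
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %s: %d genes x %d samples (%d control / %d case), %s scale\n",
    x$metadata$study_id, nrow(x$values), ncol(x$values),
    x$metadata$n_control, x$metadata$n_case, x$scale))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Canonical expression TSV dialect: row 1 "sample_id" + sample IDs, row 2
# "group" + control/case labels, then one row per gene.  Missing values are
# written as "NA".

#' Read an expression study from the canonical TSV dialect
#'
#' The canonical dialect is tab-separated with two header rows: the first
#' holds sample identifiers, the second the per-sample group labels
#' (`control`/`case`, introduced by the literal field `group`); every
#' following row is a gene symbol and its values. Missing values are `NA`.
#'
#' @param path Path to a TSV file in the canonical dialect.
#' @param metadata The study's metadata record; group counts in the file
#'   must match it.
#' @return An [expression_study()].
#' @seealso [write_expression_study()] for the exact inverse.
#' @export
read_expression_study <- function(path, metadata) {
  lines <- readLines(path)
  megax_check(length(lines) >= 3L,
              sprintf("%s: expected 2 header rows plus at least one gene row",
                      path), "megax_format_error")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  if (any(lengths(cells) != width))
    megax_stop(sprintf("%s: line %d has %d fields, expected %d", path,
                       which(lengths(cells) != width)[1L],
                       lengths(cells)[which(lengths(cells) != width)[1L]],
                       width),
               "megax_format_error")
  megax_check(cells[[2L]][1L] == "group",
              sprintf("%s: second row must start with 'group'", path),
              "megax_format_error")
  samples <- cells[[1L]][-1L]
  group <- cells[[2L]][-1L]
  genes <- vapply(cells[-(1:2)], `[[`, character(1L), 1L)
  values <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(cells[-(1:2)], `[`, -1L)))),
    nrow = length(genes), byrow = TRUE,
    dimnames = list(genes, samples))
  expression_study(metadata, values, group)
}

#' Write an expression study in the canonical TSV dialect
#'
#' Numbers are formatted with 17 significant digits (`%.17g`), which
#' round-trips doubles exactly: write-read cycles reproduce the matrix
#' bit for bit and rewriting a read file is byte-identical.
#'
#' @param study An [expression_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_study <- function(study, path) {
  megax_check(inherits(study, "expression_study"),
              "study must be an expression_study", "megax_validation_error")
  samples <- colnames(study$values) %||%
    sprintf("S%d", seq_len(ncol(study$values)))
  header <- paste(c("sample_id", samples), collapse = "\t")
  groups <- paste(c("group", study$group), collapse = "\t")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  body <- vapply(seq_len(nrow(study$values)), function(i) {
    paste(c(study$genes[i], fmt(study$values[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, groups, body), path)
  invisible(path)
}

#' Read a study-metadata table
#'
#' Expects a tab-separated file with header columns `study_id`,
#' `n_control`, `n_case`, `country`, `study_age_years`, `organism` (the
#' fields of the packaged LSCC study table; see [lscc_fixture()]).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one validated row per study, in file order.
#' @export
read_study_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("study_id", "n_control", "n_case")
  megax_check(all(need %in% names(tab)),
              sprintf("%s: missing required column(s): %s", path,
                      paste(setdiff(need, names(tab)), collapse = ", ")),
              "megax_format_error")
  if (nrow(tab) == 0L)
    return(study_metadata("dummy", 1, 1)[0L, ])
  for (cc in c("n_control", "n_case")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v) || any(v != floor(v)))
      megax_stop(sprintf("%s: column %s must contain integers", path, cc),
                 "megax_format_error")
  }
  megax_check(!anyDuplicated(tab$study_id),
              sprintf("%s: duplicated study_id", path),
              "megax_validation_error")
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    study_metadata(tab$study_id[i], tab$n_control[i], tab$n_case[i],
                   country = tab$country[i] %||% NA,
                   study_age_years =
                     suppressWarnings(as.numeric(tab$study_age_years[i])),
                   organism = tab$organism[i] %||% NA)
  }))
  rownames(out) <- NULL
  out
}

#' Read a signed literature-relation table
#'
#' Tab-separated with header columns `source`, `target`, `polarity`,
#' `relation_kind`, `provenance`. Polarity may be written `+`, `-`, `+1`
#' or `-1`; `relation_kind` is `regulation` (driver to gene) or
#' `disease_association` (disease to gene, or gene to disease).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of validated relations with integer `polarity`
#'   in `{-1, +1}`; `(source, target, relation_kind)` is unique.
#' @export
read_relation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("source", "target", "polarity", "relation_kind")
  megax_check(all(need %in% names(tab)),
              sprintf("%s: missing required column(s): %s", path,
                      paste(setdiff(need, names(tab)), collapse = ", ")),
              "megax_format_error")
  pol <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L,
           "1" = 1L)[tab$polarity]
  if (anyNA(pol) && nrow(tab) > 0L)
    megax_stop(sprintf("%s: polarity must be one of +, -, +1, -1 (got '%s')",
                       path, tab$polarity[which(is.na(pol))[1L]]),
               "megax_format_error")
  key <- paste(tab$source, tab$target, tab$relation_kind, sep = "\r")
  if (anyDuplicated(key))
    megax_stop(sprintf("%s: duplicated relation (%s)", path,
                       gsub("\r", ", ", key[duplicated(key)][1L],
                            fixed = TRUE)),
               "megax_validation_error")
  data.frame(source = tab$source, target = tab$target,
             polarity = as.integer(pol),
             relation_kind = tab$relation_kind,
             provenance = tab$provenance %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated as name,
#' description/external ID, then member gene symbols. Duplicate members
#' within a set are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets; each element is a list with `name`,
#'   `external_id` and a character vector `members`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    megax_check(length(f) >= 3L,
                sprintf("%s: line %d has fewer than 3 fields", path, i),
                "megax_format_error")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    megax_check(length(members) > 0L,
                sprintf("%s: line %d (%s) has no members", path, i, f[1L]),
                "megax_format_error")
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': removed %d duplicated member(s)",
                      f[1L], sum(duplicated(members))), call. = FALSE)
      members <- unique(members)
    }
    list(name = f[1L], external_id = f[2L], members = members)
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Packaged LSCC fixtures
#'
#' Paths to the small plain-text fixtures shipped with the package: the
#' 12-study LSCC study-metadata table, the signed relation tables behind
#' the diagnostic (contra-directional marker) and prognostic (regulator
#' chain) networks around driver PPARG and disease LSCC, and a small
#' synthetic GO-style GMT collection for enrichment examples.
#'
#' @param name One of `"study_table"`, `"diagnostic_relations"`,
#'   `"prognostic_relations"`, `"gene_sets"`.
#' @return The on-disk path of the fixture.
#' @export
lscc_fixture <- function(name = c("study_table", "diagnostic_relations",
                                  "prognostic_relations", "gene_sets")) {
  name <- match.arg(name)
  file <- switch(name,
    study_table = "lscc_study_table.tsv",
    diagnostic_relations = "lscc_diagnostic_relations.tsv",
    prognostic_relations = "lscc_prognostic_relations.tsv",
    gene_sets = "synthetic_go_sets.gmt")
  path <- system.file("extdata", file, package = "megax", mustWork = TRUE)
  path
}

#' Read or write a per-study effect table
#'
#' Effect tables are tab-separated with columns `study_id`, `gene`, `lfc`,
#' `se`, `n_control`, `n_case` (one row per study and gene), the interchange
#' format between the effect-size and pooling stages.
#'
#' @param path TSV path.
#' @return For `read_effect_table`, a validated effect `data.frame`.
#' @export
read_effect_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "gene", "lfc", "se")
  megax_check(all(need %in% names(tab)),
              sprintf("%s: missing required column(s): %s", path,
                      paste(setdiff(need, names(tab)), collapse = ", ")),
              "megax_format_error")
  megax_check(is.numeric(tab$lfc) && is.numeric(tab$se),
              sprintf("%s: lfc and se must be numeric", path),
              "megax_format_error")
  tab
}

#' @param effects An effect `data.frame`.
#' @rdname read_effect_table
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
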