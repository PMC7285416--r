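#' @noRd
mega_result_json <- function(x) {
  list(gene = x$gene, model = x$model, k_studies = x$k_studies,
       pooled_lfc = x$pooled_lfc, se = x$se,
       ci95 = list(low = x$ci95[1L], high = x$ci95[2L]),
       p_value = x$p_value,
       het = unclass(x$het),
       studies_used = as.list(x$studies_used),
       forest = x$study_data)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with fields
#' `study_table_path`, exactly one of `expression_dir` / `effects_path`,
#' `genes` (genes of interest), `partial_fraction` (default 0.5),
#' `mlr_factors`, `relation_path`, `gmt_path`, `driver`, `disease`,
#' `output_dir` and `seed`. `relation_path`, `gmt_path` and `mlr_factors`
#' are optional; the corresponding stages are skipped when absent.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  megax_check(is.list(config), "config must be a list or YAML path",
              "megax_validation_error")
  has_expr <- !is.null(config$expression_dir)
  has_eff <- !is.null(config$effects_path)
  megax_check(xor(has_expr, has_eff),
              "exactly one of expression_dir / effects_path must be set",
              "megax_validation_error")
  megax_check(!is.null(config$study_table_path),
              "study_table_path is required", "megax_validation_error")
  megax_check(!is.null(config$output_dir), "output_dir is required",
              "megax_validation_error")
  ## YAML deserializes sequences as lists; flatten the vector-valued fields
  config$genes <- if (!is.null(config$genes)) unlist(config$genes)
  config$mlr_factors <- if (!is.null(config$mlr_factors))
    unlist(config$mlr_factors)
  config$partial_fraction <- config$partial_fraction %||% 0.5
  megax_check(config$partial_fraction > 0 && config$partial_fraction <= 1,
              "partial_fraction must be in (0, 1]",
              "megax_validation_error")
  config$driver <- config$driver %||% "PPARG"
  config$disease <- config$disease %||% "LSCC"
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full mega-analysis pipeline
#'
#' Orchestrates effects -> mega + partial mega-analysis -> covariate MLR
#' -> diagnostic/prognostic networks -> over-representation analysis from
#' one configuration, writing TSV/JSON outputs and a machine-readable
#' manifest into `output_dir`. Reruns with identical inputs and seed
#' produce identical outputs (the manifest carries no timestamps).
#'
#' Outputs: `effects.tsv`, `mega.json`, `mlr.tsv` (when `mlr_factors`
#' set), `network_diagnostic.{tsv,json}` and `network_prognostic.{tsv,json}`
#' (when `relation_path` set), `enrich_diagnostic.tsv` and
#' `enrich_prognostic.tsv` (when additionally `gmt_path` set), and
#' `manifest.json` with input MD5 hashes, package version and seed.
#'
#' @param config See [run_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- function(f) file.path(config$output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, megax_error = function(e) {
      megax_stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
                 class(e)[1L])
    })
  }

  studies <- stage("study_table", read_study_table(config$study_table_path))
  inputs <- c(study_table = config$study_table_path)

  effects <- stage("effects", {
    if (!is.null(config$effects_path)) {
      inputs <<- c(inputs, effects = config$effects_path)
      read_effect_table(config$effects_path)
    } else {
      paths <- file.path(config$expression_dir,
                         paste0(studies$study_id, ".tsv"))
      inputs <<- c(inputs, stats::setNames(paths, studies$study_id))
      coll <- lapply(seq_len(nrow(studies)), function(i)
        read_expression_study(paths[i], studies[i, , drop = FALSE]))
      coll <- lapply(coll, function(s)
        if (identical(s$scale, "linear")) to_log2(s) else s)
      compute_collection_effects(coll, genes = config$genes)
    }
  })
  if (!is.null(config$genes))
    effects <- effects[effects$gene %in% config$genes, , drop = FALSE]
  write_effect_table(effects, out("effects.tsv"))

  mega <- stage("mega_analysis",
                mega_analyze_genes(effects, config$partial_fraction))
  jsonlite::write_json(
    lapply(mega, function(g) list(full = mega_result_json(g$full),
                                  partial = mega_result_json(g$partial))),
    out("mega.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  mlr <- NULL
  if (!is.null(config$mlr_factors)) {
    mlr <- stage("mlr", lapply(mega_names <- names(mega), function(g)
      fit_mlr(effects[effects$gene == g, , drop = FALSE], studies,
              factors = config$mlr_factors)))
    names(mlr) <- names(mega)
    tab <- do.call(rbind, lapply(mlr, function(m)
      data.frame(gene = m$gene, factor = names(m$factor_p),
                 p_value = unname(m$factor_p), r2 = m$r2,
                 n_studies = m$n_studies, row.names = NULL)))
    utils::write.table(tab, out("mlr.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  diagnostic <- prognostic <- NULL
  if (!is.null(config$relation_path)) {
    inputs <- c(inputs, relations = config$relation_path)
    relations <- stage("relations", read_relation_table(config$relation_path))
    full_mega <- lapply(mega, `[[`, "full")
    diagnostic <- stage("diagnostic_network", build_diagnostic_network(
      relations, config$driver, config$disease, mega = full_mega))
    prognostic <- stage("prognostic_network", build_prognostic_network(
      relations, config$driver, config$disease, mega = full_mega))
    for (nm in c("diagnostic", "prognostic")) {
      net <- if (nm == "diagnostic") diagnostic else prognostic
      utils::write.table(net$edges, out(sprintf("network_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        lapply(unclass(net), function(v)
          if (is.data.frame(v)) v else as.list(v)),
        out(sprintf("network_%s.json", nm)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  enr <- list()
  if (!is.null(config$gmt_path) && !is.null(diagnostic)) {
    inputs <- c(inputs, gene_sets = config$gmt_path)
    sets <- stage("gene_sets", read_gene_sets(config$gmt_path))
    set_genes <- unique(unlist(lapply(sets, `[[`, "members")))
    queries <- list(
      diagnostic = consistent_markers(diagnostic),
      prognostic = unique(c(config$driver, prognostic$promoters,
                            prognostic$inhibitors)))
    for (nm in names(queries)) {
      if (length(queries[[nm]]) == 0L) next
      enr[[nm]] <- stage(paste0("enrich_", nm), enrich(
        queries[[nm]], sets,
        universe = union(set_genes, queries[[nm]])))
      utils::write.table(enr[[nm]], out(sprintf("enrich_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package = "megax",
    version = as.character(utils::packageVersion("megax")),
    seed = config$seed,
    partial_fraction = config$partial_fraction,
    genes = as.list(unique(effects$gene)),
    inputs = lapply(stats::setNames(as.list(inputs), names(inputs)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = as.list(list.files(config$output_dir)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(studies = studies, effects = effects, mega = mega,
                 mlr = mlr, diagnostic = diagnostic,
                 prognostic = prognostic, enrichment = enr,
                 manifest = manifest))
}
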