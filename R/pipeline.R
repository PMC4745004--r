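#' Configuration for a full pipeline run
#'
#' Collects the inputs and tuning parameters for [run_pipeline()]. Inputs
#' may be given either as file paths (wide profile TSV, interaction TSV,
#' GMT) or as already-loaded objects; control and test sample id sets must
#' be non-empty and disjoint.
#'
#' @param profiles Path to a wide profile TSV, or a named list of
#'   [expression_profile()] objects.
#' @param interactions Path to an interaction TSV, or an
#'   [interaction_table()].
#' @param gene_sets Path to a GMT file, or a [pathway_collection()].
#' @param control_ids,test_ids Character vectors of sample ids.
#' @param alpha Significance level for the differential Z-tests (default
#'   0.05).
#' @param enrich_alpha Significance level for pathway enrichment (default
#'   0.05).
#' @param adjust Logical; use BH q-values for the significance decisions
#'   (default `FALSE`, mirroring an uncorrected screen).
#' @param direction Which significant features count as screen hits:
#'   `"repressed"` (default) keeps only features whose repression share
#'   *increased* in the test sample — the workflow looks for mRNAs that
#'   tumour miRNAs repress more, and because shares sum to one, any gain by
#'   the truly affected genes forces a compensating significant loss on
#'   everything else, which a two-sided screen would sweep in —
#'   `"both"` keeps every significant feature regardless of sign.
#' @param outdir Optional directory; when given, every intermediate table
#'   plus a JSON run manifest is written there.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(profiles, interactions, gene_sets,
                       control_ids, test_ids,
                       alpha = 0.05, enrich_alpha = 0.05,
                       adjust = FALSE, direction = c("repressed", "both"),
                       outdir = NULL) {
  direction <- match.arg(direction)
  control_ids <- as.character(control_ids)
  test_ids <- as.character(test_ids)
  if (!length(control_ids) || !length(test_ids)) {
    stop("control and test id sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(control_ids, test_ids))) {
    stop("control and test id sets must be disjoint", call. = FALSE)
  }
  structure(list(profiles = profiles, interactions = interactions,
                 gene_sets = gene_sets, control_ids = control_ids,
                 test_ids = test_ids, alpha = alpha,
                 enrich_alpha = enrich_alpha, adjust = adjust,
                 direction = direction, outdir = outdir),
            class = "run_config")
}

#' Run the full repression-profiling workflow
#'
#' Executes the four-step analysis end to end: (1) TPM normalization of
#' every profile and averaging of the control samples into a single control
#' profile; (2) score-proportional repression accumulation per sample;
#' (3) per-test-sample differential Z-tests against the control, at both
#' the mRNA and the miRNA-mRNA interaction level — each tumour sample is
#' compared independently against the one averaged control, and recurrence
#' is taken across samples afterwards; (4) hypergeometric pathway
#' enrichment of each sample's significant genes, intersection of enriched
#' pathways across samples, restriction of the interaction-level results to
#' those overlapped pathways, and recurrence summaries of the miRNAs and
#' mRNAs significant there in every sample.
#'
#' The enrichment universe is every gene of the interaction table annotated
#' to at least one pathway; per-sample hits are intersected with it.
#'
#' @param config A [run_config()].
#' @return A list of class `"pipeline_result"`: `control` (averaged
#'   [normalized_profile()]), `repression` / `contributions` /
#'   `diff_genes` / `diff_interactions` / `enrichment` (named per-sample
#'   lists), `overlapped_pathways`, `restricted_interactions` (per-sample),
#'   `recurrent_mirnas` and `recurrent_genes`
#'   ([recurrent_elements()] summaries), and `manifest` (stage-by-stage
#'   counts and parameters). With `config$outdir` set, all tables and
#'   `manifest.json` are also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  profiles <- stage("read_profiles", {
    if (is.character(config$profiles)) read_profiles(config$profiles)
    else config$profiles
  })
  interactions <- stage("read_interactions", {
    if (is.character(config$interactions))
      read_interactions(config$interactions)
    else config$interactions
  })
  pathways <- stage("read_gene_sets", {
    if (is.character(config$gene_sets)) read_gene_sets(config$gene_sets)
    else config$gene_sets
  })
  missing_ids <- setdiff(c(config$control_ids, config$test_ids),
                         names(profiles))
  if (length(missing_ids)) {
    stop("sample id(s) not in profiles: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  # step 1: normalization and averaged control
  tpm <- stage("normalize", lapply(profiles, tpm_normalize))
  control <- stage("average_controls",
                   average_controls(tpm[config$control_ids]))

  # step 2: repression accumulation
  weights <- stage("target_weights", target_weights(interactions))
  control_rep <- repression_scores(control, weights)
  control_contrib <- interaction_contributions(control, weights)
  repression <- lapply(tpm[config$test_ids], repression_scores, weights)
  contributions <- lapply(tpm[config$test_ids],
                          interaction_contributions, weights)

  # step 3: per-sample differential analysis versus the averaged control
  diff_genes <- stage("differential_genes",
    lapply(repression, function(r)
      differential_repression(control_rep, r, alpha = config$alpha,
                              adjust = config$adjust)))
  diff_inter <- stage("differential_interactions",
    lapply(contributions, function(ct)
      differential_interactions(control_contrib, ct,
                                alpha = config$alpha,
                                adjust = config$adjust)))

  # step 4: enrichment, overlap, pathway-restricted recurrence
  annotated <- pathway_genes(pathways)
  universe <- intersect(unique(interactions$gene_id), annotated)
  if (!length(universe)) {
    stop("no interaction gene is annotated to any pathway", call. = FALSE)
  }
  is_hit <- function(d) {
    if (config$direction == "repressed") {
      d$significant & d$p_hat_2 > d$p_hat_1
    } else {
      d$significant
    }
  }
  enrichment <- stage("enrichment", lapply(diff_genes, function(d) {
    hits <- intersect(d$gene_id[is_hit(d)], universe)
    hypergeom_enrich(hits, pathways, universe,
                     alpha = config$enrich_alpha, adjust = config$adjust)
  }))
  overlapped <- stage("overlapped_pathways", overlapped_pathways(enrichment))
  restricted <- lapply(diff_inter, restrict_to_pathways, pathways,
                       overlapped)
  mirna_sets <- lapply(restricted, function(d)
    unique(d$mirna_id[is_hit(d)]))
  gene_sets_sig <- lapply(diff_genes, function(d) {
    restr <- restrict_to_pathways(d, pathways, overlapped)
    unique(restr$gene_id[is_hit(restr)])
  })
  recurrent_mirnas <- recurrent_elements(mirna_sets)
  recurrent_genes <- recurrent_elements(gene_sets_sig)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirepress")),
    parameters = list(alpha = config$alpha,
                      enrich_alpha = config$enrich_alpha,
                      adjust = config$adjust,
                      direction = config$direction,
                      control_ids = config$control_ids,
                      test_ids = config$test_ids),
    counts = list(
      n_profiles = length(profiles),
      n_mirnas = length(unique(unlist(lapply(profiles, function(p)
        names(p$counts)), use.names = FALSE))),
      n_interactions = nrow(interactions),
      n_pathways = length(pathways),
      universe_size = length(universe),
      n_significant_genes = vapply(diff_genes, function(d)
        sum(d$significant), 0L),
      n_significant_interactions = vapply(diff_inter, function(d)
        sum(d$significant), 0L),
      n_enriched_pathways = vapply(enrichment, function(e)
        sum(e$enriched), 0L),
      n_overlapped_pathways = length(overlapped),
      n_restricted_interactions = vapply(restricted, nrow, 0L),
      n_recurrent_mirnas = length(recurrent_mirnas$intersection),
      n_recurrent_genes = length(recurrent_genes$intersection)),
    overlapped_pathways = overlapped)

  result <- structure(list(control = control,
                           repression = repression,
                           contributions = contributions,
                           diff_genes = diff_genes,
                           diff_interactions = diff_inter,
                           enrichment = enrichment,
                           overlapped_pathways = overlapped,
                           restricted_interactions = restricted,
                           recurrent_mirnas = recurrent_mirnas,
                           recurrent_genes = recurrent_genes,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, tpm, config)
  result
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_pipeline_outputs <- function(result, tpm, config) {
  dir <- config$outdir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_profiles(tpm, file.path(dir, "tpm.tsv"))
  write_profiles(list(result$control), file.path(dir, "control.tsv"))
  for (sid in names(result$diff_genes)) {
    write_result_table(result$diff_genes[[sid]],
                       file.path(dir, paste0("diff_genes_", sid, ".tsv")))
    write_result_table(result$diff_interactions[[sid]],
                       file.path(dir,
                                 paste0("diff_interactions_", sid, ".tsv")))
    write_result_table(result$enrichment[[sid]],
                       file.path(dir, paste0("enrichment_", sid, ".tsv")))
  }
  jsonlite::write_json(result$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
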