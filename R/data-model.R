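#' mirepress: abundance-weighted miRNA target repression profiling
#'
#' Core workflow: [tpm_normalize()] and [average_controls()] put raw miRNA
#' count profiles on the transcripts-per-million scale and build an averaged
#' control; [target_weights()] and [repression_scores()] apportion each
#' miRNA's abundance across its predicted targets in proportion to repression
#' scores and accumulate a per-mRNA repression mass; [differential_repression()]
#' and [differential_interactions()] compare repression shares between a test
#' sample and the control with a pooled two-proportion Z-test;
#' [hypergeom_enrich()], [overlapped_pathways()], [restrict_to_pathways()] and
#' [recurrent_elements()] find pathways perturbed in every sample and the
#' miRNAs/mRNAs recurrently implicated there; [panel_matrix()] and
#' [hierarchical_cluster()] evaluate miRNA biomarker panels;
#' [simulate_dataset()] generates benchmark data with planted signal; and
#' [run_pipeline()] orchestrates the whole analysis.
#'
#' @keywords internal
"_PACKAGE"

#' Construct an expression profile
#'
#' A raw miRNA expression profile for one sample: a named vector of
#' non-negative transcript counts (or any non-negative abundance measure),
#' one entry per miRNA.
#'
#' @param sample_id Single character string identifying the sample.
#' @param counts Named numeric vector of non-negative abundances; names are
#'   miRNA identifiers and must be unique. At least one entry must be
#'   positive.
#' @return An object of class `"expression_profile"`: a list with elements
#'   `sample_id` and `counts`.
#' @examples
#' expression_profile("s1", c("miR-a" = 10, "miR-b" = 30))
#' @export
expression_profile <- function(sample_id, counts) {
  check_sample_id(sample_id)
  counts <- check_abundances(counts, what = "counts")
  if (!any(counts > 0)) {
    stop("profile '", sample_id, "' has no positive counts", call. = FALSE)
  }
  structure(list(sample_id = sample_id, counts = counts),
            class = "expression_profile")
}

#' Construct a TPM-normalized profile
#'
#' Holds transcripts-per-million abundances for one sample. The values must
#' sum to one million (relative tolerance 1e-9); use [tpm_normalize()] to
#' build one from raw counts.
#'
#' @param sample_id Single character string identifying the sample.
#' @param tpm Named numeric vector of non-negative TPM values summing to 1e6.
#' @return An object of class `"normalized_profile"`: a list with elements
#'   `sample_id` and `tpm`.
#' @seealso [tpm_normalize()], [average_controls()]
#' @export
normalized_profile <- function(sample_id, tpm) {
  check_sample_id(sample_id)
  tpm <- check_abundances(tpm, what = "tpm")
  total <- sum(tpm)
  if (abs(total - 1e6) > 1e-9 * 1e6) {
    stop("TPM values of '", sample_id, "' sum to ", format(total),
         ", not 1e6", call. = FALSE)
  }
  structure(list(sample_id = sample_id, tpm = tpm),
            class = "normalized_profile")
}

#' Construct a miRNA-mRNA interaction table
#'
#' Validates a table of predicted miRNA-to-mRNA interactions carrying
#' non-negative repression scores (e.g. preprocessed miRanda output).
#' Raw miRanda emits both positive alignment scores and negative binding
#' energies; converting either into a non-negative repression score is the
#' caller's responsibility before the table enters the package.
#'
#' @param records Data frame with character columns `mirna_id`, `gene_id`
#'   and numeric column `score`. `(mirna_id, gene_id)` pairs must be unique
#'   and scores non-negative.
#' @return The validated data frame with class
#'   `c("interaction_table", "data.frame")`.
#' @export
interaction_table <- function(records) {
  if (!is.data.frame(records)) {
    stop("interaction records must be a data frame", call. = FALSE)
  }
  needed <- c("mirna_id", "gene_id", "score")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("interaction table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[needed]
  records$mirna_id <- as.character(records$mirna_id)
  records$gene_id <- as.character(records$gene_id)
  if (!nrow(records) && !is.numeric(records$score)) {
    records$score <- numeric(0L)  # header-only input has untyped columns
  }
  if (!is.numeric(records$score) || anyNA(records$score)) {
    stop("interaction scores must be numeric and non-missing", call. = FALSE)
  }
  if (any(records$score < 0)) {
    bad <- which(records$score < 0)[1L]
    stop("negative repression score at row ", bad, " (",
         records$mirna_id[bad], " -> ", records$gene_id[bad], "): ",
         records$score[bad], call. = FALSE)
  }
  key <- paste(records$mirna_id, records$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate interaction pair: ",
         sub("\r", " -> ", dup, fixed = TRUE), call. = FALSE)
  }
  rownames(records) <- NULL
  class(records) <- c("interaction_table", "data.frame")
  records
}

#' Construct a pathway collection
#'
#' A set of named pathways, each with a description and a deduplicated gene
#' set, as carried by GMT files.
#'
#' @param pathways Named list; each element is a list with elements `name`
#'   (description string) and `genes` (character vector, at least one gene).
#'   List names are pathway identifiers and must be unique.
#' @return An object of class `"pathway_collection"`.
#' @export
pathway_collection <- function(pathways) {
  if (!is.list(pathways) || is.null(names(pathways)) ||
      any(!nzchar(names(pathways)))) {
    stop("pathways must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(pathways))) {
    stop("duplicate pathway id: ",
         names(pathways)[duplicated(names(pathways))][1L], call. = FALSE)
  }
  ids <- names(pathways)
  cleaned <- lapply(seq_along(pathways), function(i) {
    pw <- pathways[[i]]
    if (!is.list(pw) || is.null(pw$genes)) {
      stop("pathway '", ids[i], "' must be a list with a 'genes' element",
           call. = FALSE)
    }
    genes <- unique(as.character(pw$genes))
    if (!length(genes)) {
      stop("pathway '", ids[i], "' has no genes", call. = FALSE)
    }
    list(name = if (is.null(pw$name)) ids[i] else as.character(pw$name)[1L],
         genes = genes)
  })
  names(cleaned) <- ids
  structure(cleaned, class = "pathway_collection")
}

#' Union of gene sets over selected pathways
#'
#' @param pathways A [pathway_collection()].
#' @param ids Character vector of pathway identifiers; defaults to all.
#' @return Character vector: the union of the selected pathways' gene sets.
#' @export
pathway_genes <- function(pathways, ids = names(pathways)) {
  stopifnot(inherits(pathways, "pathway_collection"))
  unknown <- setdiff(ids, names(pathways))
  if (length(unknown)) {
    stop("unknown pathway id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unique(unlist(lapply(pathways[ids], `[[`, "genes"), use.names = FALSE))
}

# -- internal validators ------------------------------------------------------

check_sample_id <- function(sample_id) {
  if (!is.character(sample_id) || length(sample_id) != 1L ||
      is.na(sample_id) || !nzchar(sample_id)) {
    stop("sample_id must be a single non-empty string", call. = FALSE)
  }
  invisible(sample_id)
}

check_abundances <- function(x, what = "counts") {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named numeric vector", call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contain missing values", call. = FALSE)
  if (any(x < 0)) {
    bad <- names(x)[x < 0][1L]
    stop("negative ", what, " for miRNA '", bad, "'", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate miRNA id '", names(x)[duplicated(names(x))][1L],
         "' in ", what, call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
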