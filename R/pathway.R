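#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with `N` objects, `K` of them
#' special, and `n` drawn without replacement — the enrichment p-value for
#' observing at least `k` pathway genes among `n` hits. Vectorized over all
#' arguments.
#'
#' @param k Observed overlap count(s).
#' @param K Pathway size(s) within the universe.
#' @param N Universe size(s).
#' @param n Number of hits drawn.
#' @return Upper-tail probabilities in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway enrichment
#'
#' One-sided over-representation test: for each pathway, the probability of
#' drawing at least the observed overlap when `|hits|` genes are sampled
#' without replacement from the universe, i.e. the upper tail
#' `P(X >= k)` of a hypergeometric with universe size `N`, pathway size
#' `K = |pathway ∩ universe|` and draw size `n = |hits|`. Pathways are
#' intersected with the universe before testing; genes outside the universe
#' never count.
#'
#' @param hits Character vector of significant gene ids; must be a subset
#'   of `universe`.
#' @param pathways A [pathway_collection()].
#' @param universe Character vector: the background gene set.
#' @param alpha Significance level; a pathway is `enriched` when its raw
#'   upper-tail p-value falls below `alpha` (no multiplicity correction by
#'   default, see `adjust`).
#' @param adjust Logical; decide enrichment on BH q-values instead.
#' @return A data frame of class `c("enrichment_result", "data.frame")`
#'   with columns `pathway_id`, `overlap_count`, `pathway_size`,
#'   `hit_count`, `universe_size`, `p_value`, `enriched`.
#' @examples
#' pw <- pathway_collection(list(P1 = list(name = "toy",
#'                                         genes = paste0("g", 1:5))))
#' hypergeom_enrich(paste0("g", 1:5), pw, paste0("g", 1:20))
#' @export
hypergeom_enrich <- function(hits, pathways, universe, alpha = 0.05,
                             adjust = FALSE) {
  stopifnot(inherits(pathways, "pathway_collection"))
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (length(setdiff(hits, universe))) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(pathways), function(id) {
    pw_genes <- intersect(pathways[[id]]$genes, universe)
    K <- length(pw_genes)
    k <- length(intersect(pw_genes, hits))
    p <- hypergeom_tail(k, K, N, n)
    data.frame(pathway_id = id, overlap_count = k, pathway_size = K,
               hit_count = n, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  q <- bh_adjust(out$p_value)
  out$enriched <- (if (adjust) q else out$p_value) < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pathways enriched in every sample
#'
#' The intersection of the enriched pathway sets across all per-sample
#' enrichment results: the "overlapped" pathways that every tumour sample
#' perturbs. Adding a sample can only shrink or preserve the result.
#'
#' @param per_sample Non-empty named list of [hypergeom_enrich()] results.
#' @return Character vector of pathway ids (sorted).
#' @export
overlapped_pathways <- function(per_sample) {
  if (!is.list(per_sample) || !length(per_sample)) {
    stop("need at least one enrichment result", call. = FALSE)
  }
  sets <- lapply(per_sample, function(er) {
    stopifnot(inherits(er, "enrichment_result"))
    er$pathway_id[er$enriched]
  })
  sort(Reduce(intersect, sets))
}

#' Restrict a differential table to selected pathways
#'
#' Keeps only rows whose gene (for interaction-level tables, the
#' interaction's gene) belongs to the union of the selected pathways' gene
#' sets, preserving row order.
#'
#' @param diff A differential table from [differential_repression()] or
#'   [differential_interactions()].
#' @param pathways A [pathway_collection()].
#' @param selected Character vector of pathway ids; must all exist in
#'   `pathways`.
#' @return The filtered differential table.
#' @export
restrict_to_pathways <- function(diff, pathways, selected) {
  stopifnot(inherits(diff, "differential_table"))
  if (!length(selected)) {
    out <- diff[0L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  genes <- pathway_genes(pathways, selected)  # validates `selected`
  out <- diff[diff$gene_id %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-sample recurrence of elements
#'
#' Summarizes how a family of per-sample element sets (e.g. significant
#' miRNAs per tumour sample) overlaps: the intersection over all samples
#' (the recurrent elements) and the size of every occupied Venn region,
#' keyed by the sorted sample ids that share the region (joined with
#' `"&"`). Region counts sum to the size of the union.
#'
#' @param per_sample_sets Non-empty named list of character vectors.
#' @return An object of class `"recurrence_summary"`: a list with
#'   `per_sample_sets`, `intersection`, and `region_counts` (named integer
#'   vector).
#' @export
recurrent_elements <- function(per_sample_sets) {
  if (!is.list(per_sample_sets) || !length(per_sample_sets) ||
      is.null(names(per_sample_sets))) {
    stop("need a non-empty named list of sets", call. = FALSE)
  }
  sets <- lapply(per_sample_sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  signature <- vapply(universe, function(el) {
    members <- names(sets)[vapply(sets, function(s) el %in% s, TRUE)]
    paste(sort(members), collapse = "&")
  }, "")
  counts <- if (length(universe)) {
    tab <- table(signature)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0L), character(0L))
  }
  structure(list(per_sample_sets = sets,
                 intersection = sort(Reduce(intersect, sets)),
                 region_counts = counts),
            class = "recurrence_summary")
}

#' Count each miRNA's targets inside selected pathways
#'
#' For every selected pathway and every miRNA of interest, counts how many
#' of the miRNA's predicted target genes lie in that pathway's gene set.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param interactions An [interaction_table()].
#' @param pathways A [pathway_collection()].
#' @param selected Character vector of pathway ids to tally over.
#' @return Integer matrix with one row per selected pathway and one column
#'   per miRNA.
#' @export
count_targets_per_pathway <- function(mirnas, interactions, pathways,
                                      selected) {
  stopifnot(inherits(interactions, "interaction_table"))
  unknown <- setdiff(selected, names(pathways))
  if (length(unknown)) {
    stop("unknown pathway id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mirnas <- unique(as.character(mirnas))
  out <- matrix(0L, nrow = length(selected), ncol = length(mirnas),
                dimnames = list(selected, mirnas))
  for (pw in selected) {
    genes <- pathways[[pw]]$genes
    sub <- interactions[interactions$mirna_id %in% mirnas &
                          interactions$gene_id %in% genes, ]
    if (nrow(sub)) {
      tab <- table(factor(sub$mirna_id, levels = mirnas))
      out[pw, ] <- as.integer(tab)
    }
  }
  out
}
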