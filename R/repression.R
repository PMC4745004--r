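#' Score-proportional target weights
#'
#' For each miRNA, divides every interaction's repression score by the sum
#' of that miRNA's scores over all its targets, so the weights describe how
#' the miRNA's abundance is apportioned across its target mRNAs:
#' `weight(a, g) = RS(a, g) / sum_t RS(a, t)`. A miRNA whose scores sum to
#' zero predicts no repression anywhere; such miRNAs are dropped with a
#' warning rather than given uniform weights.
#'
#' @param interactions An [interaction_table()].
#' @return A data frame of class `c("weight_table", "data.frame")` with
#'   columns `mirna_id`, `gene_id`, `weight`; for every retained miRNA the
#'   weights sum to 1 (tolerance 1e-12).
#' @examples
#' it <- interaction_table(data.frame(
#'   mirna_id = c("a", "a"), gene_id = c("alpha", "beta"),
#'   score = c(60, 40)))
#' target_weights(it)  # weights 0.6 and 0.4
#' @export
target_weights <- function(interactions) {
  stopifnot(inherits(interactions, "interaction_table"))
  if (!nrow(interactions)) {
    out <- data.frame(mirna_id = character(), gene_id = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("weight_table", "data.frame")
    return(out)
  }
  totals <- tapply(interactions$score, interactions$mirna_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    warning("dropping ", length(zero),
            " miRNA(s) with all-zero repression scores: ",
            paste(zero, collapse = ", "), call. = FALSE)
  }
  keep <- !(interactions$mirna_id %in% zero)
  out <- data.frame(
    mirna_id = interactions$mirna_id[keep],
    gene_id = interactions$gene_id[keep],
    weight = interactions$score[keep] /
      as.vector(totals[interactions$mirna_id[keep]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Accumulated per-mRNA repression of a profile
#'
#' The comprehensive repression an mRNA receives is the sum, over all
#' miRNAs targeting it, of the miRNA's TPM abundance times its
#' score-proportional weight on that mRNA:
#' `R(g) = sum_a tpm(a) * weight(a, g)`. Abundance is apportioned, never
#' created, so the total repression equals the summed TPM of every
#' target-bearing miRNA present in the profile. miRNAs in the profile
#' without targets contribute nothing; weighted miRNAs absent from the
#' profile contribute zero.
#'
#' @param profile A [normalized_profile()].
#' @param weights A weight table from [target_weights()].
#' @return An object of class `"repression_result"`: a list with
#'   `sample_id`, `repression` (named numeric, one entry per targeted gene)
#'   and `total` (sum of all entries).
#' @export
repression_scores <- function(profile, weights) {
  stopifnot(inherits(profile, "normalized_profile"),
            inherits(weights, "weight_table"))
  contrib <- interaction_contributions(profile, weights)
  if (!nrow(contrib)) {
    rep <- stats::setNames(numeric(0L), character(0L))
  } else {
    agg <- tapply(contrib$contribution, contrib$gene_id, sum)
    rep <- stats::setNames(as.vector(agg), names(agg))
  }
  repression_result(profile$sample_id, rep)
}

#' Construct a repression result
#'
#' Container for the accumulated per-mRNA repression of one sample; usually
#' produced by [repression_scores()] rather than built directly.
#'
#' @param sample_id Single character string.
#' @param repression Named numeric vector of non-negative per-gene
#'   repression masses.
#' @return An object of class `"repression_result"` with elements
#'   `sample_id`, `repression`, and `total = sum(repression)`.
#' @export
repression_result <- function(sample_id, repression) {
  check_sample_id(sample_id)
  if (length(repression)) {
    if (!is.numeric(repression) || is.null(names(repression))) {
      stop("repression must be a named numeric vector", call. = FALSE)
    }
    if (anyNA(repression) || any(repression < 0)) {
      stop("repression values must be non-negative and non-missing",
           call. = FALSE)
    }
    if (anyDuplicated(names(repression))) {
      stop("duplicate gene id in repression vector", call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id,
                 repression = repression,
                 total = sum(repression)),
            class = "repression_result")
}

#' Per-interaction repression contributions
#'
#' The repression mass each individual miRNA-mRNA interaction carries:
#' `contribution(a, g) = tpm(a) * weight(a, g)`. Summing contributions over
#' miRNAs for a gene reproduces [repression_scores()] for that gene.
#'
#' @inheritParams repression_scores
#' @return A data frame of class `c("contribution_table", "data.frame")`
#'   with columns `mirna_id`, `gene_id`, `contribution` and attribute
#'   `sample_id`.
#' @export
interaction_contributions <- function(profile, weights) {
  stopifnot(inherits(profile, "normalized_profile"),
            inherits(weights, "weight_table"))
  tpm <- profile$tpm[weights$mirna_id]
  tpm[is.na(tpm)] <- 0
  out <- data.frame(mirna_id = weights$mirna_id,
                    gene_id = weights$gene_id,
                    contribution = as.vector(tpm) * weights$weight,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sample_id") <- profile$sample_id
  class(out) <- c("contribution_table", "data.frame")
  out
}
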