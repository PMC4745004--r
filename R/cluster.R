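#' Sample-by-panel expression matrix
#'
#' Extracts a panel of miRNAs from a set of TPM profiles and applies the
#' variance-compressing `log2(tpm + 1)` transform. A panel miRNA absent
#' from a profile enters as `log2(0 + 1) = 0`, so the matrix never has
#' missing entries.
#'
#' @param profiles Non-empty list of [normalized_profile()] objects.
#' @param panel Non-empty ordered character vector of miRNA ids.
#' @return Numeric matrix with one row per sample (rownames = sample ids)
#'   and one column per panel miRNA (colnames = panel).
#' @export
panel_matrix <- function(profiles, panel) {
  if (!length(panel)) stop("empty panel", call. = FALSE)
  if (!is.list(profiles) || !length(profiles)) {
    stop("need at least one profile", call. = FALSE)
  }
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("duplicate miRNA in panel", call. = FALSE)
  rows <- vapply(profiles, function(p) {
    stopifnot(inherits(p, "normalized_profile"))
    v <- p$tpm[panel]
    v[is.na(v)] <- 0
    log2(as.vector(v) + 1)
  }, numeric(length(panel)))
  mat <- t(matrix(rows, nrow = length(panel)))
  dimnames(mat) <- list(vapply(profiles, `[[`, "", "sample_id"), panel)
  mat
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the rows (samples) of a panel matrix with agglomerative
#' hierarchical clustering. Distances are either Euclidean or correlation
#' distance (`1 - Pearson r` between sample rows); linkage is average,
#' complete or single. The merge tree and the partition at every cut
#' `k = 1..n` are returned; the agglomeration is deterministic, so
#' identical input yields an identical tree.
#'
#' @param matrix Numeric matrix, samples in rows (at least 2), as from
#'   [panel_matrix()].
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An object of class `"clustering_result"`: a list with
#'   `merge_tree` (data frame `node_a`, `node_b`, `height`; negative nodes
#'   are original samples, positive nodes earlier merges), `labels_at_k`
#'   (list; element `k` is a named integer vector assigning every sample a
#'   cluster index in `1..k`), and the underlying [stats::hclust] object as
#'   `hclust`.
#' @export
hierarchical_cluster <- function(matrix,
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("average", "complete",
                                             "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("need a numeric matrix of samples x features", call. = FALSE)
  }
  n <- nrow(matrix)
  if (n < 2L) stop("clustering needs at least 2 samples", call. = FALSE)
  d <- switch(distance,
              euclidean = stats::dist(matrix, method = "euclidean"),
              correlation = stats::as.dist(1 - stats::cor(t(matrix))))
  hc <- stats::hclust(d, method = linkage)
  heights <- hc$height
  labels_at_k <- lapply(seq_len(n), function(k) {
    cut <- stats::cutree(hc, k = k)
    names(cut) <- rownames(matrix)
    cut
  })
  names(labels_at_k) <- as.character(seq_len(n))
  structure(list(
    merge_tree = data.frame(node_a = hc$merge[, 1L],
                            node_b = hc$merge[, 2L],
                            height = heights),
    labels_at_k = labels_at_k,
    hclust = hc), class = "clustering_result")
}

#' Purity of a clustering against known groups
#'
#' Fraction of samples lying in a cluster whose majority truth group is
#' their own: `purity = sum_c max_g |c ∩ g| / n`. Purity 1 means every
#' cluster is homogeneous; a single all-encompassing cluster over two equal
#' groups scores 0.5.
#'
#' @param labels Named vector: cluster index per sample (e.g. one element
#'   of `labels_at_k`).
#' @param truth Named vector: true group per sample; must cover exactly the
#'   same sample ids.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(labels, truth) {
  if (is.null(names(labels)) || is.null(names(truth)) ||
      !setequal(names(labels), names(truth)) ||
      length(labels) != length(truth)) {
    stop("labels and truth must cover the same sample ids", call. = FALSE)
  }
  truth <- truth[names(labels)]
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / length(labels)
}
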