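#' Pooled two-proportion Z-test
#'
#' Tests whether a feature's share of its group total differs between two
#' groups. With observed masses `x1`, `x2` out of group totals `n1`, `n2`,
#' the group shares are `p1 = x1/n1` and `p2 = x2/n2`, the pooled share is
#' `p0 = (x1 + x2) / (n1 + n2)`, and
#' `z = (p1 - p2) / sqrt(p0 * (1 - p0) * (1/n1 + 1/n2))`,
#' referred two-sided to the standard normal. Masses may be real-valued
#' (here they are repression masses on the TPM scale), so the "sample
#' sizes" are the group totals of that mass.
#'
#' When the pooled share is degenerate (`p0` equal to 0 or 1) the statistic
#' is undefined; `z` is returned as `NA` with a p-value of 1, so degenerate
#' features are never called significant.
#'
#' @param x1,x2 Non-negative feature masses in group 1 and group 2.
#' @param n1,n2 Positive group totals, with `x1 <= n1`, `x2 <= n2`.
#' @return An object of class `"ztest_result"`: a list with elements
#'   `p_hat_1`, `p_hat_2`, `p0`, `z`, `p_value`.
#' @examples
#' two_proportion_z(30, 100, 10, 100)  # z = 3.5355, p = 4.07e-4
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(length(x1) == 1L, length(n1) == 1L,
            length(x2) == 1L, length(n2) == 1L)
  res <- ztest_vectorized(x1, n1, x2, n2)
  structure(list(p_hat_1 = res$p_hat_1, p_hat_2 = res$p_hat_2,
                 p0 = res$p0, z = res$z, p_value = res$p_value),
            class = "ztest_result")
}

# vectorized core shared by the scalar test and the differential tables
ztest_vectorized <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("group totals must be positive", call. = FALSE)
  }
  if (any(x1 < 0) || any(x2 < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (any(x1 > n1) || any(x2 > n2)) {
    stop("feature mass exceeds its group total", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  p0 <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, NA_real_)
  p <- ifelse(is.na(z), 1, 2 * stats::pnorm(-abs(z)))
  data.frame(p_hat_1 = p1, p_hat_2 = p2, p0 = p0, z = z, p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values. Thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`; every q-value is at least its
#' p-value and at most 1, and the result is equivariant under permutation
#' of the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential repression between a control and a test sample
#'
#' For every gene in the union of the two repression results, applies the
#' pooled two-proportion Z-test ([two_proportion_z()]) to the gene's
#' repression mass out of its group's total repression; a gene absent from
#' one group enters with mass 0. Significance defaults to the raw two-sided
#' p-value falling below `alpha`; with `adjust = TRUE` the decision uses
#' the Benjamini-Hochberg q-value instead (q-values are reported either
#' way).
#'
#' @param control,test [repression_scores()] results; both totals must be
#'   positive.
#' @param alpha Significance level (default 0.05).
#' @param adjust Logical; decide significance on BH q-values instead of raw
#'   p-values.
#' @return A data frame of class `c("differential_table", "data.frame")`
#'   with columns `gene_id`, `x_control`, `x_test`, `p_hat_1` (control
#'   share), `p_hat_2` (test share), `p0`, `z`, `p_value`, `q_value`,
#'   `significant`, ordered by gene id.
#' @export
differential_repression <- function(control, test, alpha = 0.05,
                                    adjust = FALSE) {
  stopifnot(inherits(control, "repression_result"),
            inherits(test, "repression_result"))
  if (control$total <= 0 || test$total <= 0) {
    stop("both groups need positive total repression", call. = FALSE)
  }
  keys <- sort(unique(c(names(control$repression), names(test$repression))))
  x1 <- vec_at(control$repression, keys)
  x2 <- vec_at(test$repression, keys)
  build_differential_table(keys, "gene_id", x1, control$total,
                           x2, test$total, alpha, adjust)
}

#' Differential repression of individual miRNA-mRNA interactions
#'
#' As [differential_repression()], but each key is a (miRNA, mRNA)
#' interaction and masses come from [interaction_contributions()]; group
#' totals are each table's total contribution.
#'
#' @param control,test [interaction_contributions()] tables.
#' @inheritParams differential_repression
#' @return A data frame of class `c("differential_table", "data.frame")`
#'   with columns `mirna_id`, `gene_id`, then the same statistics columns
#'   as [differential_repression()]. Empty inputs yield an empty table.
#' @export
differential_interactions <- function(control, test, alpha = 0.05,
                                      adjust = FALSE) {
  stopifnot(inherits(control, "contribution_table"),
            inherits(test, "contribution_table"))
  key1 <- paste(control$mirna_id, control$gene_id, sep = "\r")
  key2 <- paste(test$mirna_id, test$gene_id, sep = "\r")
  keys <- sort(unique(c(key1, key2)))
  if (!length(keys)) {
    out <- build_differential_table(character(), "key", numeric(), 1,
                                    numeric(), 1, alpha, adjust)
    return(split_interaction_keys(out))
  }
  n1 <- sum(control$contribution)
  n2 <- sum(test$contribution)
  if (n1 <= 0 || n2 <= 0) {
    stop("both groups need positive total contribution", call. = FALSE)
  }
  x1 <- vec_at(stats::setNames(control$contribution, key1), keys)
  x2 <- vec_at(stats::setNames(test$contribution, key2), keys)
  out <- build_differential_table(keys, "key", x1, n1, x2, n2, alpha, adjust)
  split_interaction_keys(out)
}

vec_at <- function(v, keys) {
  out <- v[keys]
  out[is.na(out)] <- 0
  as.vector(out)
}

build_differential_table <- function(keys, key_col, x1, n1, x2, n2,
                                     alpha, adjust) {
  if (length(keys)) {
    stats_df <- ztest_vectorized(x1, n1, x2, n2)
    q <- bh_adjust(stats_df$p_value)
    crit <- if (adjust) q else stats_df$p_value
    out <- data.frame(key = keys, x_control = x1, x_test = x2,
                      stats_df, q_value = q,
                      significant = crit < alpha,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(key = character(), x_control = numeric(),
                      x_test = numeric(), p_hat_1 = numeric(),
                      p_hat_2 = numeric(), p0 = numeric(), z = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  }
  names(out)[1L] <- key_col
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

split_interaction_keys <- function(tab) {
  parts <- strsplit(tab$key, "\r", fixed = TRUE)
  tab$key <- NULL
  out <- data.frame(mirna_id = vapply(parts, `[[`, "", 1L),
                    gene_id = vapply(parts, function(p)
                      if (length(p) > 1L) p[[2L]] else "", ""),
                    tab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}
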