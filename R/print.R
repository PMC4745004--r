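#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> sample", x$sample_id, "-", length(x$counts),
      "miRNAs, total count", format(sum(x$counts)), "\n")
  invisible(x)
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat("<normalized_profile> sample", x$sample_id, "-", length(x$tpm),
      "miRNAs (TPM)\n")
  invisible(x)
}

#' @export
print.repression_result <- function(x, ...) {
  cat("<repression_result> sample", x$sample_id, "-",
      length(x$repression), "genes, total repression",
      format(x$total), "\n")
  invisible(x)
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf(
    "<ztest_result> p1 = %.4g, p2 = %.4g, p0 = %.4g, z = %s, p = %.4g\n",
    x$p_hat_1, x$p_hat_2, x$p0,
    if (is.na(x$z)) "undefined" else sprintf("%.4f", x$z), x$p_value))
  invisible(x)
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- lengths(lapply(unclass(x), `[[`, "genes"))
  cat("<pathway_collection>", length(x), "pathways,",
      sum(sizes), "gene annotations (set sizes ", min(sizes), "-",
      max(sizes), ")\n", sep = " ")
  invisible(x)
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat("<recurrence_summary>", length(x$per_sample_sets), "samples;",
      length(x$intersection), "recurrent elements;",
      length(x$region_counts), "occupied Venn regions\n")
  invisible(x)
}

#' @export
print.literature_summary <- function(x, ...) {
  cat(sprintf(
    "<literature_summary> %d miRNAs: %d unreported (%.1f%%); of %d reported, %d consistent (%.1f%%), %d inconsistent (%.1f%%)\n",
    x$n_total, x$n_unreported, x$pct_unreported, x$n_reported,
    x$n_consistent, x$pct_consistent, x$n_inconsistent,
    x$pct_inconsistent))
  if (length(x$inconsistent_mirnas)) {
    cat("  inconsistent:", paste(x$inconsistent_mirnas, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$profiles), "profiles (",
      x$config$n_control, "control /", x$config$n_test, "test ),",
      nrow(x$interactions), "interactions,", length(x$pathways),
      "pathways;", length(x$truth$pathways), "planted pathways,",
      length(x$truth$mirnas), "planted miRNAs\n")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  c <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat("  samples:", length(x$repression), "test vs averaged control\n")
  cat("  significant genes per sample:",
      paste(c$n_significant_genes, collapse = ", "), "\n")
  cat("  overlapped pathways:",
      if (length(x$overlapped_pathways))
        paste(x$overlapped_pathways, collapse = ", ") else "(none)", "\n")
  cat("  recurrent miRNAs:", c$n_recurrent_mirnas,
      "| recurrent genes:", c$n_recurrent_genes, "\n")
  invisible(x)
}
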