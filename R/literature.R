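#' Read a literature-report table
#'
#' Parses a two-column TSV of miRNA ids and their reported expression
#' directions in the disease literature. The `reports` field is a
#' comma-separated list of `up` / `down` calls, one per published report;
#' a missing or empty field means the miRNA has no reports (printed as
#' "NULL" in curated tables).
#'
#' @param path Path to the TSV (header `mirna_id`, `reports`).
#' @return A list of class `"literature_table"`: one character vector of
#'   directions per miRNA, named by miRNA id (possibly length 0).
#' @seealso [literature_reports()] for the packaged 21-miRNA curation.
#' @export
read_literature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty literature table", call. = FALSE)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA id '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  reports <- lapply(fields, function(f) {
    if (length(f) < 2L || !nzchar(f[[2L]])) return(character(0L))
    dirs <- trimws(strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])
    bad <- setdiff(dirs, c("up", "down"))
    if (length(bad)) {
      stop("unknown report direction '", bad[1L], "' for ", f[[1L]],
           call. = FALSE)
    }
    dirs
  })
  names(reports) <- ids
  structure(reports, class = "literature_table")
}

#' Packaged literature curation of the 21 recurrent miRNAs
#'
#' The curated table of published expression-direction reports for the 21
#' miRNAs recurrently implicated across tumour samples, shipped with the
#' package as a plain-text fixture. Three miRNAs (hsa-miR-16-2*,
#' hsa-miR-30c-2*, hsa-miR-592) have no reports; hsa-miR-17 and
#' hsa-miR-215 carry reports in both directions.
#'
#' @return A `"literature_table"` (see [read_literature_table()]).
#' @export
literature_reports <- function() {
  read_literature_table(system.file("extdata", "table1_reports.tsv",
                                    package = "mirepress",
                                    mustWork = TRUE))
}

#' Tabulate literature report coverage and consistency
#'
#' Counts how many miRNAs lack any report, and, among reported miRNAs, how
#' many have a single consistent change direction across all their reports
#' versus a mixed (inconsistent) one. The unreported percentage is taken
#' over all miRNAs; the consistency percentages over the reported miRNAs
#' only. Percentages are rounded half-up to one decimal.
#'
#' @param table A `"literature_table"`.
#' @return A list of class `"literature_summary"` with `n_total`,
#'   `n_unreported`, `n_reported`, `n_consistent`, `n_inconsistent`,
#'   `pct_unreported`, `pct_consistent`, `pct_inconsistent`, and
#'   `inconsistent_mirnas` (ids with mixed directions).
#' @export
tabulate_literature <- function(table) {
  stopifnot(inherits(table, "literature_table"))
  n_total <- length(table)
  reported <- table[lengths(table) > 0L]
  n_reported <- length(reported)
  consistent <- vapply(reported,
                       function(d) length(unique(d)) == 1L, TRUE)
  n_consistent <- sum(consistent)
  pct <- function(num, den) {
    if (den == 0L) return(0)
    floor(num / den * 1000 + 0.5) / 10  # half-up to one decimal
  }
  structure(list(
    n_total = n_total,
    n_unreported = n_total - n_reported,
    n_reported = n_reported,
    n_consistent = n_consistent,
    n_inconsistent = n_reported - n_consistent,
    pct_unreported = pct(n_total - n_reported, n_total),
    pct_consistent = pct(n_consistent, n_reported),
    pct_inconsistent = pct(n_reported - n_consistent, n_reported),
    inconsistent_mirnas = sort(names(reported)[!consistent])),
    class = "literature_summary")
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative qPCR quantification: the target gene's cycle
#' threshold is normalized to a reference gene within each condition
#' (`dCt = Ct_target - Ct_reference`), the control condition's dCt is
#' subtracted from the test condition's (`ddCt`), and the fold change is
#' `2^(-ddCt)`. One fewer cycle of ddCt doubles the fold change exactly.
#'
#' @param ct_target_test,ct_reference_test Ct of target and reference gene
#'   in the test condition.
#' @param ct_target_control,ct_reference_control Ct in the control
#'   condition.
#' @return Positive fold change.
#' @examples
#' ddct_fold_change(25, 20, 26, 20)  # ddCt = -1, fold change 2
#' @export
ddct_fold_change <- function(ct_target_test, ct_reference_test,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_test, ct_reference_test,
           ct_target_control, ct_reference_control)
  if (length(cts) != 4L || !is.numeric(cts) || any(!is.finite(cts))) {
    stop("all four Ct values must be single finite numbers", call. = FALSE)
  }
  ddct <- (ct_target_test - ct_reference_test) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
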