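#' Read miRNA expression profiles from a wide TSV
#'
#' The carrier format is a tab-separated table whose first column holds
#' miRNA identifiers (header `mirna_id` by convention, but any header is
#' accepted for that column) and whose remaining columns are samples of
#' non-negative abundances. Identifiers are matched by exact, case-sensitive
#' string equality throughout the package.
#'
#' @param path Path to the TSV file.
#' @return A named list of [expression_profile()] objects, one per sample
#'   column, in column order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("mirna_id\ts1\ts2", "miR-a\t10\t0", "miR-b\t30\t5"), tf)
#' read_profiles(tf)
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("profile table needs a miRNA-id column plus >= 1 sample column",
         call. = FALSE)
  }
  mirna_ids <- tab[[1L]]
  if (anyDuplicated(mirna_ids)) {
    stop("duplicate miRNA id '", mirna_ids[duplicated(mirna_ids)][1L],
         "' in ", path, call. = FALSE)
  }
  samples <- names(tab)[-1L]
  profiles <- lapply(samples, function(s) {
    raw <- tab[[s]]
    vals <- suppressWarnings(as.numeric(raw))
    if (anyNA(vals)) {
      i <- which(is.na(vals))[1L]
      stop("non-numeric value '", raw[i], "' at miRNA '", mirna_ids[i],
           "', sample '", s, "'", call. = FALSE)
    }
    if (any(vals < 0)) {
      i <- which(vals < 0)[1L]
      stop("negative value at miRNA '", mirna_ids[i], "', sample '", s, "'",
           call. = FALSE)
    }
    names(vals) <- mirna_ids
    expression_profile(s, vals)
  })
  names(profiles) <- samples
  profiles
}

#' Write expression or normalized profiles to a wide TSV
#'
#' Writes the inverse of [read_profiles()]: one row per miRNA (union of all
#' ids, in first appearance order; ids absent from a profile are written as
#' 0), one column per sample. Accepts raw ([expression_profile()]) and
#' TPM ([normalized_profile()]) objects alike.
#'
#' @param profiles List of `expression_profile` or `normalized_profile`
#'   objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  vecs <- lapply(profiles, profile_values)
  ids <- unique(unlist(lapply(vecs, names), use.names = FALSE))
  mat <- vapply(vecs, function(v) {
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(v)] <- v
    out
  }, numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, vapply(profiles, `[[`,
                                            "", "sample_id")))
  tab <- data.frame(mirna_id = ids, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

profile_values <- function(p) {
  if (inherits(p, "expression_profile")) return(p$counts)
  if (inherits(p, "normalized_profile")) return(p$tpm)
  stop("not a profile object", call. = FALSE)
}

#' Read a scored miRNA-mRNA interaction table
#'
#' Expects a TSV with header columns `mirna_id`, `gene_id`, `score`
#' (non-negative repression scores; see [interaction_table()] for the
#' miRanda preprocessing contract). A header-only file yields an empty
#' table, under which all downstream repression is zero.
#'
#' @param path Path to the TSV file.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  interaction_table(tab)
}

#' Write an interaction table to TSV
#'
#' @param interactions An [interaction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  stopifnot(inherits(interactions, "interaction_table"))
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one pathway per line; tab-separated fields are the
#' pathway id, a free-text description, then one or more gene ids. Genes are
#' deduplicated within each pathway.
#'
#' @param path Path to the GMT file.
#' @return A [pathway_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  pws <- lapply(fields, function(f) list(name = f[[2L]], genes = f[-(1:2)]))
  names(pws) <- ids
  pathway_collection(pws)
}

#' Write gene sets to a GMT file
#'
#' @param pathways A [pathway_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- vapply(names(pathways), function(id) {
    pw <- pathways[[id]]
    paste(c(id, pw$name, pw$genes), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Generic writer for the package's data-frame results (differential tables,
#' enrichment tables, weight tables).
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
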