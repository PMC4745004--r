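#' TPM-normalize a raw expression profile
#'
#' Rescales each miRNA's transcript count to transcripts per million:
#' `tpm(a) = counts(a) / sum(counts) * 1e6`. The transform is invariant to
#' multiplying all counts by a positive constant, so library size drops out.
#' Zero-count miRNAs are kept as explicit zero entries so that downstream
#' set operations over miRNA ids are well defined.
#'
#' @param profile An [expression_profile()].
#' @return A [normalized_profile()] on the same miRNA ids.
#' @examples
#' p <- expression_profile("s1", c(a = 3, b = 1))
#' tpm_normalize(p)$tpm  # a = 750000, b = 250000
#' @export
tpm_normalize <- function(profile) {
  stopifnot(inherits(profile, "expression_profile"))
  total <- sum(profile$counts)
  if (total <= 0) {
    stop("cannot normalize empty profile '", profile$sample_id, "'",
         call. = FALSE)
  }
  normalized_profile(profile$sample_id, profile$counts / total * 1e6)
}

#' Average normalized profiles into a single control profile
#'
#' Computes the per-miRNA arithmetic mean of TPM values over the union of
#' miRNA ids (a miRNA absent from a profile contributes 0 for that profile).
#' Averaging happens on the TPM scale, not the raw-count scale, so samples
#' with unequal library sizes carry equal weight in the control. Because
#' every input sums to one million, so does the average.
#'
#' @param profiles Non-empty list of [normalized_profile()] objects.
#' @param sample_id Identifier for the averaged profile.
#' @return A [normalized_profile()].
#' @export
average_controls <- function(profiles, sample_id = "control_mean") {
  if (!is.list(profiles) || !length(profiles)) {
    stop("need at least one profile to average", call. = FALSE)
  }
  ok <- vapply(profiles, inherits, TRUE, "normalized_profile")
  if (!all(ok)) stop("all profiles must be normalized_profile", call. = FALSE)
  ids <- unique(unlist(lapply(profiles, function(p) names(p$tpm)),
                       use.names = FALSE))
  acc <- stats::setNames(numeric(length(ids)), ids)
  for (p in profiles) acc[names(p$tpm)] <- acc[names(p$tpm)] + p$tpm
  mean_tpm <- acc / length(profiles)
  # guard against float drift so the constructor's sum invariant holds
  mean_tpm <- mean_tpm / sum(mean_tpm) * 1e6
  normalized_profile(sample_id, mean_tpm)
}
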