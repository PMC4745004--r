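#' Configuration for the synthetic dataset generator
#'
#' Bundles and validates the parameters of [simulate_dataset()]. The
#' defaults emulate the structure of the study design the package targets:
#' a few hundred miRNAs, a scored bipartite target network over ~1000
#' genes, 20 disjoint pathways, 4 control and 4 tumour samples, and 4
#' planted pathways whose dedicated miRNAs are both rewired into the
#' pathway and up-regulated fourfold in every tumour sample.
#'
#' @param n_mirnas Number of miRNAs (default 300).
#' @param n_genes Number of genes (default 1000).
#' @param n_pathways Number of disjoint pathways partitioning the genes
#'   (default 20).
#' @param targets_per_mirna Length-2 integer range for each miRNA's target
#'   count (default `c(5, 15)`).
#' @param score_range Length-2 positive range for uniform repression scores
#'   (default `c(50, 200)`, miRanda-alignment-score scale).
#' @param n_control,n_test Number of control / tumour samples (default 4
#'   each).
#' @param baseline_mean Centre of the log-uniform distribution of per-miRNA
#'   baseline mean counts (default 100; means span one decade either side).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`; default 0.1, typical miRNA-seq
#'   overdispersion).
#' @param planted_pathways Number of pathways carrying planted signal
#'   (default 4).
#' @param planted_mirnas_per_pathway miRNAs rewired into (and up-regulated
#'   for) each planted pathway (default 5).
#' @param fold_change Multiplier applied to planted miRNAs' mean counts in
#'   tumour samples (default 4; 1 gives a null dataset).
#' @param seed Integer master seed (default 7).
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_mirnas = 300L, n_genes = 1000L,
                             n_pathways = 20L,
                             targets_per_mirna = c(5L, 15L),
                             score_range = c(50, 200),
                             n_control = 4L, n_test = 4L,
                             baseline_mean = 100, dispersion = 0.1,
                             planted_pathways = 4L,
                             planted_mirnas_per_pathway = 5L,
                             fold_change = 4, seed = 7L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              targets_per_mirna = as.integer(targets_per_mirna),
              score_range = as.numeric(score_range),
              n_control = as.integer(n_control),
              n_test = as.integer(n_test),
              baseline_mean = as.numeric(baseline_mean),
              dispersion = as.numeric(dispersion),
              planted_pathways = as.integer(planted_pathways),
              planted_mirnas_per_pathway =
                as.integer(planted_mirnas_per_pathway),
              fold_change = as.numeric(fold_change),
              seed = as.integer(seed))
  with(cfg, {
    if (n_mirnas < 1L || n_genes < 1L || n_pathways < 1L ||
        n_control < 1L || n_test < 1L || planted_pathways < 0L ||
        planted_mirnas_per_pathway < 1L) {
      stop("all counts must be >= 1 (planted_pathways may be 0)",
           call. = FALSE)
    }
    if (length(targets_per_mirna) != 2L ||
        targets_per_mirna[1L] > targets_per_mirna[2L] ||
        targets_per_mirna[1L] < 1L) {
      stop("targets_per_mirna must be an increasing range >= 1",
           call. = FALSE)
    }
    if (targets_per_mirna[2L] > n_genes) {
      stop("targets_per_mirna max exceeds n_genes", call. = FALSE)
    }
    if (length(score_range) != 2L || score_range[1L] <= 0 ||
        score_range[1L] > score_range[2L]) {
      stop("score_range must be a positive increasing range", call. = FALSE)
    }
    if (planted_pathways > n_pathways) {
      stop("planted_pathways exceeds n_pathways", call. = FALSE)
    }
    if (planted_pathways * planted_mirnas_per_pathway > n_mirnas) {
      stop("not enough miRNAs to plant", call. = FALSE)
    }
    if (n_pathways > n_genes) {
      stop("more pathways than genes", call. = FALSE)
    }
    if (baseline_mean <= 0 || dispersion <= 0 || fold_change <= 0) {
      stop("baseline_mean, dispersion and fold_change must be positive",
           call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic miRNA repression benchmark dataset
#'
#' Produces raw count profiles, a scored miRNA-mRNA interaction network,
#' disjoint pathway annotations and a ground-truth manifest. Per-miRNA
#' baseline means are drawn log-uniformly over one decade either side of
#' `baseline_mean`; counts are negative-binomial with the configured
#' dispersion. Each miRNA targets a uniform-random gene set (sizes uniform
#' in `targets_per_mirna`) with scores uniform in `score_range`. Genes are
#' partitioned into `n_pathways` disjoint pathways. For every planted
#' pathway, `planted_mirnas_per_pathway` dedicated miRNAs are rewired so at
#' least 80% of their targets lie inside the pathway, and their mean counts
#' are multiplied by `fold_change` in tumour samples only.
#'
#' Three independent RNG streams (network, planting, expression) are
#' derived from the master seed, so a change to one component's parameters
#' leaves the draws of the others untouched; the same configuration always
#' reproduces the identical dataset. The function uses and then restores
#' R's global RNG state.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"synthetic_dataset"` with elements `profiles`
#'   (named list of [expression_profile()]; controls first, then tumours),
#'   `interactions` ([interaction_table()]), `pathways`
#'   ([pathway_collection()]), `truth` (list: `pathways`, `mirnas`,
#'   `genes` — the planted ids), and `config`.
#' @examples
#' ds <- simulate_dataset(synthetic_config(n_mirnas = 30, n_genes = 60,
#'                                         n_pathways = 4, seed = 1))
#' names(ds$profiles)
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)

  set.seed(config$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("gene-%04d", seq_len(config$n_genes))
  pathway_ids <- sprintf("pw-%02d", seq_len(config$n_pathways))

  # -- network stream: pathway partition + random target sets -------------
  set.seed(stream_seeds[1L])
  membership <- rep(seq_len(config$n_pathways), length.out = config$n_genes)
  membership <- sample(membership)
  pw_list <- lapply(seq_len(config$n_pathways), function(i) {
    list(name = paste("synthetic pathway", i),
         genes = gene_ids[membership == i])
  })
  names(pw_list) <- pathway_ids
  pathways <- pathway_collection(pw_list)

  size_choices <- seq(config$targets_per_mirna[1L],
                      config$targets_per_mirna[2L])
  n_targets <- size_choices[sample.int(length(size_choices),
                                       config$n_mirnas, replace = TRUE)]
  targets <- lapply(n_targets, function(k) sample(gene_ids, k))
  scores <- lapply(n_targets, function(k)
    stats::runif(k, config$score_range[1L], config$score_range[2L]))

  # -- planting stream: rewire dedicated miRNAs into planted pathways -----
  set.seed(stream_seeds[2L])
  planted_pw <- character(0L)
  planted_mirna_idx <- integer(0L)
  pw_of_mirna <- character(0L)
  if (config$planted_pathways > 0L) {
    planted_pw <- sort(sample(pathway_ids, config$planted_pathways))
    n_planted <- config$planted_pathways * config$planted_mirnas_per_pathway
    planted_mirna_idx <- sort(sample.int(config$n_mirnas, n_planted))
    pw_of_mirna <- rep(planted_pw, each = config$planted_mirnas_per_pathway)
    for (j in seq_along(planted_mirna_idx)) {
      i <- planted_mirna_idx[j]
      pw_genes <- pathways[[pw_of_mirna[j]]]$genes
      k <- n_targets[i]
      k_in <- min(ceiling(0.8 * k), length(pw_genes))
      outside <- setdiff(gene_ids, pw_genes)
      k_out <- min(k - k_in, length(outside))
      targets[[i]] <- c(sample(pw_genes, k_in),
                        if (k_out > 0L) sample(outside, k_out))
      scores[[i]] <- stats::runif(length(targets[[i]]),
                                  config$score_range[1L],
                                  config$score_range[2L])
    }
  }

  interactions <- interaction_table(data.frame(
    mirna_id = rep(mirna_ids, lengths(targets)),
    gene_id = unlist(targets, use.names = FALSE),
    score = unlist(scores, use.names = FALSE),
    stringsAsFactors = FALSE))

  # -- expression stream: log-uniform baselines, NB counts ----------------
  set.seed(stream_seeds[3L])
  base_mean <- config$baseline_mean *
    10^stats::runif(config$n_mirnas, -1, 1)
  test_mean <- base_mean
  test_mean[planted_mirna_idx] <- test_mean[planted_mirna_idx] *
    config$fold_change
  size <- 1 / config$dispersion
  draw_profile <- function(sid, mu) {
    counts <- stats::rnbinom(config$n_mirnas, mu = mu, size = size)
    expression_profile(sid, stats::setNames(as.numeric(counts), mirna_ids))
  }
  profiles <- c(
    lapply(seq_len(config$n_control), function(i)
      draw_profile(sprintf("control_%d", i), base_mean)),
    lapply(seq_len(config$n_test), function(i)
      draw_profile(sprintf("tumor_%d", i), test_mean)))
  names(profiles) <- vapply(profiles, `[[`, "", "sample_id")

  planted_mirnas <- mirna_ids[planted_mirna_idx]
  planted_genes <- sort(unique(unlist(lapply(
    seq_along(planted_mirna_idx), function(j) {
      intersect(targets[[planted_mirna_idx[j]]],
                pathways[[pw_of_mirna[j]]]$genes)
    }), use.names = FALSE)))

  structure(list(profiles = profiles,
                 interactions = interactions,
                 pathways = pathways,
                 truth = list(pathways = planted_pw,
                              mirnas = planted_mirnas,
                              genes = planted_genes),
                 config = config),
            class = "synthetic_dataset")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `profiles.tsv` (wide counts), `interactions.tsv`, `pathways.gmt`
#' and `truth.json` under `dir`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(profiles = file.path(dir, "profiles.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))
  write_profiles(dataset$profiles, paths[["profiles"]])
  write_interactions(dataset$interactions, paths[["interactions"]])
  write_gene_sets(dataset$pathways, paths[["pathways"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = FALSE)
  invisible(paths)
}
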