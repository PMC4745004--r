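# small in-code fixtures and random-instance builders shared across tests

toy_profile <- function(sample_id = "s1", counts = c(a = 10, b = 30)) {
  expression_profile(sample_id, counts)
}

toy_interactions <- function() {
  interaction_table(data.frame(
    mirna_id = c("a", "a", "b"),
    gene_id = c("alpha", "beta", "alpha"),
    score = c(60, 40, 100),
    stringsAsFactors = FALSE))
}

toy_pathways <- function() {
  pathway_collection(list(
    P1 = list(name = "one", genes = c("g1", "g2")),
    P2 = list(name = "two", genes = c("g2", "g3"))))
}

# normalized-profile shell with arbitrary abundances (repression operates on
# any non-negative masses; the 1e6 sum invariant is irrelevant to it)
fake_tpm <- function(v, sample_id = "x") {
  structure(list(sample_id = sample_id, tpm = v),
            class = "normalized_profile")
}

# random profile + interaction instance for property tests; assumes the
# caller has fixed the RNG seed
random_instance <- function(n_mirnas = 20, n_genes = 30,
                            max_targets = 6) {
  mirnas <- paste0("m", seq_len(n_mirnas))
  genes <- paste0("g", seq_len(n_genes))
  counts <- stats::setNames(stats::rpois(n_mirnas, 50) + 1, mirnas)
  picks <- lapply(seq_len(n_mirnas), function(i) {
    k <- sample.int(min(max_targets, n_genes), 1L)
    sample(genes, k)
  })
  it <- interaction_table(data.frame(
    mirna_id = rep(mirnas, lengths(picks)),
    gene_id = unlist(picks, use.names = FALSE),
    score = stats::runif(sum(lengths(picks)), 0.5, 100),
    stringsAsFactors = FALSE))
  list(profile = tpm_normalize(expression_profile("r1", counts)),
       interactions = it)
}

# brute-force accumulation oracle: loop over every (miRNA, target) pair
brute_force_repression <- function(profile, interactions) {
  totals <- tapply(interactions$score, interactions$mirna_id, sum)
  rep <- stats::setNames(numeric(0L), character(0L))
  for (i in seq_len(nrow(interactions))) {
    m <- interactions$mirna_id[i]
    g <- interactions$gene_id[i]
    if (totals[[m]] == 0) next
    tpm_m <- if (m %in% names(profile$tpm)) profile$tpm[[m]] else 0
    add <- tpm_m * interactions$score[i] / totals[[m]]
    rep[g] <- (if (g %in% names(rep)) rep[[g]] else 0) + add
  }
  rep
}

# textbook pooled two-proportion computation, coded independently
oracle_ztest <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  p0 <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

# exhaustive hypergeometric upper tail from binomial-coefficient ratios
oracle_hyper_tail <- function(k, K, N, n) {
  j <- seq(from = k, to = min(K, n))
  if (!length(j) || k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# textbook BH step-up, coded independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

default_run_config <- function(ds, ...) {
  run_config(ds$profiles, ds$interactions, ds$pathways,
             control_ids = grep("^control_", names(ds$profiles),
                                value = TRUE),
             test_ids = grep("^tumor_", names(ds$profiles), value = TRUE),
             ...)
}
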