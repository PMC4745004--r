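test_that("hypergeometric enrichment reproduces exact worked values", {
  universe20 <- paste0("g", 1:20)
  pw <- pathway_collection(list(P = list(name = "p",
                                         genes = paste0("g", 1:5))))
  e <- hypergeom_enrich(paste0("g", 1:5), pw, universe20)
  expect_equal(e$p_value, 1 / 15504, tolerance = 1e-12)
  expect_true(e$enriched)

  universe10 <- paste0("g", 1:10)
  pw2 <- pathway_collection(list(P = list(name = "p",
                                          genes = paste0("g", 1:4))))
  e2 <- hypergeom_enrich(paste0("g", c(1:3, 9:10)), pw2, universe10)
  expect_equal(e2$overlap_count, 3L)
  expect_equal(e2$p_value, 66 / 252, tolerance = 1e-12)

  # pathway identical to the universe: the overlap is certain
  pw3 <- pathway_collection(list(P = list(name = "p", genes = universe10)))
  e3 <- hypergeom_enrich(paste0("g", 1:4), pw3, universe10)
  expect_equal(e3$p_value, 1)
  expect_false(e3$enriched)
})

test_that("enrichment validates hits and universe", {
  pw <- toy_pathways()
  expect_error(hypergeom_enrich("g9", pw, c("g1", "g2")), "subset")
  expect_error(hypergeom_enrich(character(), pw, character()),
               "empty universe")
})

test_that("tail p-values agree with binomial-coefficient sums", {
  for (N in c(5, 12, 23, 41, 60)) {
    universe <- paste0("g", seq_len(N))
    for (K in c(1, N %/% 3, N - 1)) {
      pw <- pathway_collection(list(P = list(name = "p",
                                             genes = universe[seq_len(K)])))
      for (n in c(1, N %/% 2, N)) {
        hits <- universe[seq_len(n)]
        e <- hypergeom_enrich(hits, pw, universe)
        k <- length(intersect(hits, universe[seq_len(K)]))
        expect_equal(e$p_value, oracle_hyper_tail(k, K, N, n),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("overlapped pathways intersect per-sample enriched sets", {
  mk <- function(ids, enriched) {
    out <- data.frame(pathway_id = ids, overlap_count = 1L,
                      pathway_size = 1L, hit_count = 1L,
                      universe_size = 2L, p_value = 0.01,
                      enriched = enriched, stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    out
  }
  one <- mk(c("P1", "P2", "P3"), c(TRUE, TRUE, FALSE))
  expect_equal(overlapped_pathways(list(s1 = one)), c("P1", "P2"))
  two <- mk(c("P1", "P2", "P3"), c(FALSE, TRUE, TRUE))
  expect_equal(overlapped_pathways(list(s1 = one, s2 = two)), "P2")
  # monotone: adding a sample can only shrink or preserve the set
  expect_true(all(overlapped_pathways(list(one, two)) %in%
                    overlapped_pathways(list(one))))
  expect_error(overlapped_pathways(list()), "at least one")
})

test_that("pathway restriction keeps exactly the covered genes, in order", {
  d <- differential_repression(
    repression_result("c", stats::setNames(rep(10, 10), paste0("g", 1:10))),
    repression_result("t", stats::setNames(rep(10, 10), paste0("g", 1:10))))
  pw <- pathway_collection(list(
    A = list(name = "a", genes = c("g2", "g5", "g7")),
    B = list(name = "b", genes = paste0("g", 1:10))))
  restricted <- restrict_to_pathways(d, pw, "A")
  expect_equal(restricted$gene_id, c("g2", "g5", "g7"))
  expect_equal(restrict_to_pathways(d, pw, c("A", "B"))$gene_id, d$gene_id)
  expect_equal(nrow(restrict_to_pathways(d, pw, character())), 0L)
  expect_error(restrict_to_pathways(d, pw, "Z"), "unknown pathway")
})

test_that("recurrence summary computes intersection and Venn regions", {
  sets <- list(s1 = c("1", "2", "3"), s2 = c("2", "3", "4"),
               s3 = c("2", "3"), s4 = c("2", "3", "5"))
  rec <- recurrent_elements(sets)
  expect_equal(rec$intersection, c("2", "3"))
  expect_equal(sum(rec$region_counts), 5L)
  expect_equal(unname(rec$region_counts["s1&s2&s3&s4"]), 2L)

  same <- recurrent_elements(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(sort(same$intersection), c("x", "y"))
  expect_equal(length(same$region_counts), 1L)

  disjoint <- recurrent_elements(list(a = "x", b = "y"))
  expect_equal(length(disjoint$intersection), 0L)
})

test_that("region counts satisfy inclusion-exclusion on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    ids <- paste0("s", 1:4)
    sets <- stats::setNames(lapply(ids, function(i)
      sample(as.character(1:15), sample(3:10, 1))), ids)
    rec <- recurrent_elements(sets)
    expect_equal(sum(rec$region_counts),
                 length(unique(unlist(sets))))
    # every pairwise intersection equals the sum of regions containing both
    for (i in 1:3) for (j in (i + 1):4) {
      both <- length(intersect(sets[[i]], sets[[j]]))
      regions <- strsplit(names(rec$region_counts), "&", fixed = TRUE)
      covered <- vapply(regions, function(r)
        all(c(ids[i], ids[j]) %in% r), TRUE)
      expect_equal(sum(rec$region_counts[covered]), both)
    }
  }
})

test_that("per-pathway target counts match a brute-force double loop", {
  expect_equal(
    count_targets_per_pathway("a", toy_interactions(),
                              pathway_collection(list(
                                P = list(name = "p",
                                         genes = c("beta", "gamma")))),
                              "P")["P", "a"], 1L)
  set.seed(32)
  inst <- random_instance(n_mirnas = 20, n_genes = 40)
  genes <- paste0("g", 1:40)
  pws <- lapply(1:4, function(i) list(name = paste0("p", i),
                                      genes = sample(genes, 10)))
  names(pws) <- paste0("P", 1:4)
  pw <- pathway_collection(pws)
  mirnas <- paste0("m", 1:20)
  got <- count_targets_per_pathway(mirnas, inst$interactions, pw,
                                   names(pw))
  for (p in names(pw)) for (m in mirnas) {
    want <- 0L
    for (r in seq_len(nrow(inst$interactions))) {
      if (inst$interactions$mirna_id[r] == m &&
          inst$interactions$gene_id[r] %in% pw[[p]]$genes) want <- want + 1L
    }
    expect_equal(got[p, m], want)
  }
})
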