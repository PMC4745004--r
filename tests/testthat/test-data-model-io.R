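test_that("wide profile TSV parses into one profile per sample column", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\ts1\ts2", "miR-a\t10\t0", "miR-b\t30\t5"), tf)
  profiles <- read_profiles(tf)
  expect_named(profiles, c("s1", "s2"))
  expect_equal(profiles$s1$counts, c("miR-a" = 10, "miR-b" = 30))
  expect_equal(profiles$s2$counts, c("miR-a" = 0, "miR-b" = 5))
})

test_that("malformed profile input is rejected with a located message", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\ts1", "miR-a\t10", "miR-a\t3"), tf)
  expect_error(read_profiles(tf), "duplicate miRNA id 'miR-a'")
  writeLines(c("mirna_id\ts1", "miR-a\tok"), tf)
  expect_error(read_profiles(tf), "non-numeric.*miR-a.*s1")
  writeLines(c("mirna_id\ts1", "miR-a\t-2"), tf)
  expect_error(read_profiles(tf), "negative.*miR-a")
  expect_error(read_profiles(file.path(tempdir(), "nope.tsv")),
               "no such file")
})

test_that("profile write-then-read reproduces all counts exactly", {
  set.seed(101)
  ids <- sprintf("miR-%02d", 1:50)
  profiles <- lapply(c("sA", "sB", "sC"), function(s)
    expression_profile(s, stats::setNames(
      sample(0:500, 50, replace = TRUE), ids)))
  names(profiles) <- c("sA", "sB", "sC")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(profiles, tf)
  back <- read_profiles(tf)
  for (s in names(profiles)) {
    expect_identical(back[[s]]$counts, profiles[[s]]$counts)
  }
})

test_that("interaction TSV parses, validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id\tscore",
               "a\talpha\t60", "a\tbeta\t40", "b\talpha\t100"), tf)
  it <- read_interactions(tf)
  expect_s3_class(it, "interaction_table")
  expect_equal(nrow(it), 3L)
  expect_equal(it$score, c(60, 40, 100))

  writeLines(c("mirna_id\tgene_id\tscore", "a\talpha\t-12.3"), tf)
  expect_error(read_interactions(tf), "negative repression score")
  writeLines(c("mirna_id\tgene_id\tscore",
               "a\talpha\t1", "a\talpha\t2"), tf)
  expect_error(read_interactions(tf), "duplicate interaction pair")

  writeLines("mirna_id\tgene_id\tscore", tf)
  empty <- read_interactions(tf)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(target_weights(empty)), 0L)

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(toy_interactions(), tf2)
  expect_equal(as.data.frame(read_interactions(tf2)),
               as.data.frame(toy_interactions()))
})

test_that("GMT parsing dedupes genes and flags malformed lines", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tg1\tg2", "P2\tdesc\tg2\tg3\tg3"), tf)
  pw <- read_gene_sets(tf)
  expect_setequal(pw$P1$genes, c("g1", "g2"))
  expect_setequal(pw$P2$genes, c("g2", "g3"))

  writeLines("P1\tdesc", tf)
  expect_error(read_gene_sets(tf), "line 1 has fewer than 3 fields")
  writeLines(c("P1\td\tg1", "P1\td\tg2"), tf)
  expect_error(read_gene_sets(tf), "duplicate pathway id")
})

test_that("a 20-pathway GMT round-trips losslessly up to gene order", {
  set.seed(7)
  pws <- lapply(1:20, function(i)
    list(name = paste("set", i),
         genes = sample(paste0("g", 1:100), sample(3:15, 1))))
  names(pws) <- sprintf("P%02d", 1:20)
  pw <- pathway_collection(pws)
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(pw, tf)
  back <- read_gene_sets(tf)
  expect_identical(names(back), names(pw))
  for (id in names(pw)) {
    expect_identical(back[[id]]$name, pw[[id]]$name)
    expect_setequal(back[[id]]$genes, pw[[id]]$genes)
  }
})

test_that("parsing is independent of input row order", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  header <- "mirna_id\tgene_id\tscore"
  body <- c("a\talpha\t60", "a\tbeta\t40", "b\talpha\t100")
  writeLines(c(header, body), tf)
  it1 <- read_interactions(tf)
  writeLines(c(header, rev(body)), tf)
  it2 <- read_interactions(tf)
  key <- function(d) d[order(d$mirna_id, d$gene_id), ]
  expect_equal(key(as.data.frame(it1)), key(as.data.frame(it2)),
               ignore_attr = TRUE)
})

test_that("type constructors enforce their invariants", {
  expect_error(expression_profile("s", c(a = 0, b = 0)),
               "no positive counts")
  expect_error(expression_profile("s", c(a = -1)), "negative counts")
  expect_error(normalized_profile("s", c(a = 1)), "sum to")
  expect_error(pathway_collection(list(P1 = list(genes = character(0)))),
               "no genes")
  expect_error(interaction_table(data.frame(mirna_id = "a", gene_id = "g")),
               "lacks column")
})
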