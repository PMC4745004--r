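test_that("pooled z-statistic matches direct evaluation", {
  res <- two_proportion_z(30, 100, 10, 100)
  expect_equal(res$p0, 0.2)
  expect_equal(res$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(res$z, 3.5355339, tolerance = 1e-6)
  expect_equal(res$p_value, 4.0695201e-4, tolerance = 1e-6)

  ident <- two_proportion_z(20, 100, 20, 100)
  expect_equal(ident$z, 0)
  expect_equal(ident$p_value, 1)
})

test_that("z is antisymmetric under group exchange", {
  set.seed(21)
  for (rep in 1:50) {
    n1 <- stats::runif(1, 10, 1e4); n2 <- stats::runif(1, 10, 1e4)
    x1 <- stats::runif(1, 0, n1);  x2 <- stats::runif(1, 0, n2)
    a <- two_proportion_z(x1, n1, x2, n2)
    b <- two_proportion_z(x2, n2, x1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate pooled proportions give undefined z, p = 1", {
  zero <- two_proportion_z(0, 50, 0, 80)
  expect_true(is.na(zero$z))
  expect_equal(zero$p_value, 1)
  one <- two_proportion_z(50, 50, 80, 80)
  expect_true(is.na(one$z))
  expect_equal(one$p_value, 1)
  expect_error(two_proportion_z(5, 0, 1, 10), "positive")
  expect_error(two_proportion_z(11, 10, 1, 10), "exceeds")
})

test_that("BH adjustment matches the textbook step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(22)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("gene-level differential table applies the z-test per gene", {
  ctrl <- repression_result("c", c(alpha = 30, beta = 70))
  test <- repression_result("t", c(alpha = 10, beta = 90))
  d <- differential_repression(ctrl, test, alpha = 0.05)
  expect_equal(d$gene_id, c("alpha", "beta"))
  expect_equal(d$z, c(3.5355339, -3.5355339), tolerance = 1e-6)
  expect_true(all(d$significant))

  same <- differential_repression(ctrl, ctrl)
  expect_true(all(same$z == 0))
  expect_false(any(same$significant))

  only_test <- differential_repression(
    repression_result("c", c(beta = 100)),
    repression_result("t", c(alpha = 10, beta = 90)))
  row <- only_test[only_test$gene_id == "alpha", ]
  expect_equal(row$x_control, 0)
  expect_false(is.na(row$z))
})

test_that("interaction-level differential finds a planted 10-fold shift", {
  set.seed(23)
  n_pairs <- 100
  mirnas <- paste0("m", rep(1:20, each = 5))
  genes <- paste0("g", rep(1:5, times = 20))
  base <- stats::runif(n_pairs, 10, 100)
  shifted <- base
  shifted[37] <- shifted[37] * 10
  make_ct <- function(v, sid) {
    out <- data.frame(mirna_id = mirnas, gene_id = genes,
                      contribution = v, stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sid
    class(out) <- c("contribution_table", "data.frame")
    out
  }
  d <- differential_interactions(make_ct(base, "c"), make_ct(shifted, "t"))
  # oracle: exhaustive per-pair evaluation of the pooled z formula
  oz <- mapply(function(x1, x2) oracle_ztest(x1, sum(base),
                                             x2, sum(shifted))$z,
               base, shifted)
  key <- paste(d$mirna_id, d$gene_id)
  expect_equal(d$z[match(paste(mirnas, genes), key)], unname(oz),
               tolerance = 1e-10)
  top <- d[which.max(abs(d$z)), ]
  expect_equal(paste(top$mirna_id, top$gene_id),
               paste(mirnas[37], genes[37]))

  single <- differential_interactions(make_ct(base, "c"), make_ct(base, "t"))
  expect_false(any(single$significant))

  empty_w <- target_weights(interaction_table(data.frame(
    mirna_id = character(), gene_id = character(), score = numeric())))
  empty <- interaction_contributions(fake_tpm(c(z = 1)), empty_w)
  expect_equal(nrow(differential_interactions(empty, empty)), 0L)
})

test_that("implementation matches the independent oracle on random draws", {
  set.seed(24)
  for (rep in 1:200) {
    n1 <- stats::runif(1, 5, 1e5); n2 <- stats::runif(1, 5, 1e5)
    x1 <- stats::runif(1, 0.01, n1 * 0.99)
    x2 <- stats::runif(1, 0.01, n2 * 0.99)
    got <- two_proportion_z(x1, n1, x2, n2)
    want <- oracle_ztest(x1, n1, x2, n2)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})
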