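test_that("outliers beyond the z-cut are replaced by the dimension median", {
  # dimension 1: population z of the extreme value is 80/36.1 ~ 2.21 > 2
  m <- cbind(c(0, 0, 0, 0, 0, 100), c(1, 2, 3, 4, 5, 6))
  out <- replace_outliers(m)
  expect_equal(out[6, 1], 0)          # replaced by median
  expect_equal(out[1:5, 1], m[1:5, 1])
  expect_equal(out[, 2], m[, 2])      # no value beyond 2 population sd
  # hand-check the z-score that triggered the replacement
  z <- abs(100 - mean(m[, 1])) / sqrt(mean((m[, 1] - mean(m[, 1]))^2))
  expect_gt(z, 2)
})

test_that("outlier replacement leaves constant and in-range dimensions alone", {
  m <- cbind(rep(3, 5), c(-1, 0, 0, 0, 1))
  expect_equal(replace_outliers(m), m)
  expect_error(replace_outliers(m[1:2, ]), "at least 3")
})

test_that("outlier replacement is idempotent once gross outliers are gone", {
  # balanced low/high dimensions with isolated gross outliers: after one
  # pass the remaining values sit within the cut, so a second pass with
  # freshly computed statistics changes nothing
  set.seed(1)
  m <- matrix(rep(c(0, 1), 50), 10, 10)
  m[3, 4] <- 100; m[7, 9] <- -100
  once <- replace_outliers(m)
  expect_equal(once[3, 4], stats::median(m[, 4]))
  expect_equal(replace_outliers(once), once)
})

test_that("PCA reduction recovers exact low-rank structure", {
  set.seed(2)
  basis <- matrix(rnorm(10 * 3), 10, 3)
  scores <- matrix(rnorm(15 * 3), 15, 3)
  m <- scores %*% t(basis) + rep(1, 15) %o% rnorm(10)  # rank-3 + offset
  red <- reduce_dims(m, 3)
  expect_equal(red$variance_explained, 1, tolerance = 1e-10)
  expect_equal(dim(red$scores), c(15L, 3L))
  expect_equal(reduce_dims(m, 10)$variance_explained, 1, tolerance = 1e-10)
})

test_that("variance explained matches an independent eigendecomposition", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10)
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  for (k in c(1, 3, 7))
    expect_equal(reduce_dims(m, k)$variance_explained,
                 sum(ev[seq_len(k)]) / sum(ev), tolerance = 1e-10)
  # non-decreasing in k
  ve <- vapply(1:9, function(k) reduce_dims(m, k)$variance_explained,
               numeric(1))
  expect_true(all(diff(ve) >= -1e-12))
  expect_error(reduce_dims(m, 25), "out of range")
})

test_that("median binarization sends ties below and splits odd dimensions", {
  expect_equal(unname(binarize_by_median(cbind(c(1, 2, 3)))[, 1]), c(0, 0, 1))
  expect_equal(unname(binarize_by_median(cbind(rep(7, 4)))[, 1]), rep(0, 4))
  expect_equal(unname(binarize_by_median(cbind(c(-5, 5)))[, 1]), c(0, 1))
  expect_equal(unname(binarize_by_median(cbind(c(1, 2, 3)), ties = "above")[, 1]),
               c(0, 1, 1))
  # odd n with distinct values -> floor(n/2) ones under strict-greater
  set.seed(4)
  m <- matrix(rnorm(35), 7, 5)
  expect_equal(unname(colSums(binarize_by_median(m))), rep(3, 5))
})

test_that("jaccard handles identity, disjoint supports, and the all-zero case", {
  expect_equal(jaccard(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(jaccard(c(0, 0), c(0, 0)), 1)
  expect_error(jaccard(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("jaccard is symmetric and bounded on random binary pairs", {
  set.seed(5)
  for (i in 1:50) {
    u <- rbinom(30, 1, 0.4); v <- rbinom(30, 1, 0.4)
    j <- jaccard(u, v)
    expect_identical(j, jaccard(v, u))
    expect_gte(j, 0); expect_lte(j, 1)
    if (all(u == v)) expect_equal(j, 1) else expect_lt(j, 1)
  }
})

test_that("jaccard_rows agrees with the scalar implementation", {
  set.seed(6)
  m <- matrix(rbinom(80, 1, 0.5), 8, 10)
  u <- rbinom(10, 1, 0.5)
  expect_equal(jaccard_rows(u, m),
               apply(m, 1, function(r) jaccard(u, r)))
})

test_that("aggregate targets concatenate segments recoverably", {
  sem <- rbinom(100, 1, 0.5); vis <- rbinom(150, 1, 0.5)
  lex <- rbinom(200, 1, 0.5)
  agg <- aggregate_target(sem, vis, lex,
                          dims = c(semantic = 100, visual = 150, lexical = 200))
  expect_length(agg, 450)
  seg <- attr(agg, "segments")
  expect_equal(agg[seg$semantic], sem, ignore_attr = TRUE)
  expect_equal(agg[seg$visual], vis, ignore_attr = TRUE)
  expect_equal(agg[seg$lexical], lex, ignore_attr = TRUE)
  expect_equal(seg$semvis, 1:250)
  expect_error(aggregate_target(sem, vis, lex[-1],
                                dims = c(semantic = 100, visual = 150,
                                         lexical = 200)),
               "lexical")
  expect_equal(sum(aggregate_target(rep(0, 3), rep(0, 2), rep(0, 4))), 0)
})

test_that("pairwise jaccard tables enumerate unordered pairs against brute force", {
  set.seed(7)
  m <- matrix(rbinom(3 * 12, 1, 0.5), 3, 12,
              dimnames = list(c("a", "b", "c"), NULL))
  tab <- pairwise_jaccard_table(m, "semantic")
  expect_equal(nrow(tab), 3)
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$jaccard[r],
                 jaccard(m[tab$item_a[r], ], m[tab$item_b[r], ]))
  # n(n-1)/2 rows, duplicated rows give index 1
  m2 <- rbind(m, d = m["a", ])
  tab2 <- pairwise_jaccard_table(m2)
  expect_equal(nrow(tab2), 6)
  expect_equal(pair_jaccard(tab2, "a", "d"), 1)
  expect_error(pairwise_jaccard_table(matrix(c(0, 0.5), 1)), "binary")
})

test_that("preprocessing pipeline orders outliers, reduction, binarization", {
  set.seed(8)
  raw <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(sprintf("i%02d", 1:30), NULL))
  raw[5, 3] <- 40
  res <- preprocess_visual(raw, k = 5)
  expect_equal(dim(res$matrix), c(30L, 5L))
  expect_true(all(res$matrix %in% c(0, 1)))
  expect_true(res$variance_explained <= 1 && res$variance_explained > 0)
  # equivalent manual composition
  manual <- binarize_by_median(reduce_dims(replace_outliers(raw), 5)$scores)
  expect_equal(unname(res$matrix), unname(manual))
  # binary semantic input passes through unchanged
  b <- matrix(rbinom(60, 1, 0.5), 10, 6)
  expect_equal(preprocess_semantic(b), b)
})
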