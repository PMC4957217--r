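# Controlled 4-sample fixture: feature values are injected directly so the
# ANOVA arithmetic can be checked against exact and oracle values.
fixture_with_features <- function(feature_values) {
  n <- nrow(feature_values)
  x <- matrix(1 / 400, nrow = n, ncol = 400L)
  x[, seq_len(ncol(feature_values))] <- feature_values
  matrix_fixture(x, rep(c("positive", "negative"), each = n / 2))
}

test_that("F is zero for equal class means and for constant features", {
  # binary-exact values: class means and grand mean are all exactly 0.5
  vals <- cbind(c(0.25, 0.75, 0.75, 0.25),   # equal means, nonzero within
                c(0.5, 0.5, 0.5, 0.5))       # constant everywhere
  f <- fscore(fixture_with_features(vals))
  expect_identical(unname(f[1L]), 0)
  expect_identical(unname(f[2L]), 0)
})

test_that("F matches the base-R ANOVA oracle and the squared pooled t", {
  withr::with_seed(31, {
    mp <- 7L; mn <- 11L
    x <- matrix(stats::runif((mp + mn) * 400L), nrow = mp + mn)
    fm <- matrix_fixture(x, rep(c("positive", "negative"), c(mp, mn)))
    f <- fscore(fm)
    for (j in sample(400L, 25L)) {
      pos <- x[1:mp, j]; neg <- x[(mp + 1):(mp + mn), j]
      expect_equal(unname(f[j]), anova_oracle_f(pos, neg),
                   tolerance = 1e-9)
      tt <- stats::t.test(pos, neg, var.equal = TRUE)$statistic
      expect_equal(unname(f[j]), unname(tt)^2, tolerance = 1e-9)
    }
  })
})

test_that("F is invariant to shifting and scaling a feature", {
  withr::with_seed(32, {
    x <- matrix(stats::runif(12 * 400), nrow = 12)
    fm <- matrix_fixture(x, rep(c("positive", "negative"), each = 6))
    f0 <- fscore(fm)
    x2 <- x; x2[, 5L] <- x2[, 5L] + 3.7; x2[, 9L] <- x2[, 9L] * -2.5
    f2 <- fscore(matrix_fixture(x2, fm$labels))
    expect_equal(unname(f2[5L]), unname(f0[5L]), tolerance = 1e-9)
    expect_equal(unname(f2[9L]), unname(f0[9L]), tolerance = 1e-9)
  })
})

test_that("perfect separators get an infinite score and rank first", {
  vals <- cbind(c(0.9, 0.9, 0.1, 0.1),      # zero within, nonzero between
                c(0.3, 0.1, 0.6, 0.4))      # ordinary finite-F feature
  fm <- fixture_with_features(vals)
  f <- fscore(fm)
  expect_identical(unname(f[1L]), Inf)
  expect_true(is.finite(f[2L]) && f[2L] > 0)
  tbl <- fscore_table(fm)
  expect_identical(tbl$rank[1L], 1L)
  expect_identical(tbl$signed_norm[1L], 1)   # separator enriched in positives
})

test_that("fscore requires two classes with at least two samples each", {
  x <- matrix(stats::runif(4 * 400), nrow = 4)
  expect_error(fscore(matrix_fixture(x, rep("positive", 4))),
               "at least 2")
  expect_error(fscore(matrix_fixture(x, c("positive", rep("negative", 3)))),
               "at least 2")
})

test_that("signed normalization maps extremes to +/-1 and zeros correctly", {
  withr::with_seed(33, {
    x <- matrix(stats::runif(20 * 400), nrow = 20)
    x[1:10, 3L] <- x[1:10, 3L] + 2    # strong positive enrichment
    x[11:20, 7L] <- x[11:20, 7L] + 2  # strong negative enrichment
    fm <- matrix_fixture(x, rep(c("positive", "negative"), each = 10))
    tbl <- fscore_table(fm)
  })
  expect_true(all(tbl$signed_norm >= -1 & tbl$signed_norm <= 1))
  top <- which.max(tbl$F)
  expect_identical(abs(tbl$signed_norm[top]), 1)
  expect_gt(tbl$signed_norm[3L], 0.5)
  expect_lt(tbl$signed_norm[7L], -0.5)
  # minimal F maps to 0 whatever its sign term
  expect_identical(tbl$signed_norm[which.min(tbl$F)], 0)
  # sign agrees with the class-mean difference everywhere
  expect_true(all(sign(tbl$signed_norm) %in% c(0, sign(tbl$mean_pos - tbl$mean_neg))))
})

test_that("a feature with equal class means has signed score of sign zero", {
  vals <- cbind(c(0.25, 0.75, 0.75, 0.25), c(0.3, 0.1, 0.6, 0.4))
  tbl <- fscore_table(fixture_with_features(vals))
  expect_identical(tbl$signed_norm[1L], 0)
})

test_that("identically-scored features cannot be normalized", {
  x <- matrix(rep(c(0.25, 0.75, 0.75, 0.25), 400), nrow = 4)
  fm <- matrix_fixture(x, rep(c("positive", "negative"), each = 2))
  expect_error(fscore_table(fm), "identical")
})

test_that("ranking is descending-F with name tie-breaks, a full permutation", {
  withr::with_seed(34, {
    x <- matrix(stats::runif(10 * 400), nrow = 10)
    fm <- matrix_fixture(x, rep(c("positive", "negative"), each = 5))
  })
  tbl <- fscore_table(fm)
  ord <- rank_features(tbl)
  expect_setequal(ord, 1:400)
  expect_true(all(diff(tbl$F[ord]) <= 0))
  expect_identical(tbl$rank[ord], 1:400)
  # forced tie: duplicate one feature's values into a later-named column
  x2 <- fm$x; x2[, "CA"] <- x2[, "AC"]
  tbl2 <- fscore_table(matrix_fixture(x2, fm$labels))
  ord2 <- rank_features(tbl2)
  expect_lt(which(ord2 == match("AC", tbl2$dipeptide)),
            which(ord2 == match("CA", tbl2$dipeptide)))
})

test_that("null F-scores have the F-distribution mean under permutation", {
  # no-signal matrix; label permutations regenerate the null many times
  withr::with_seed(35, {
    n <- 40L
    x <- matrix(stats::rnorm(n * 400), nrow = n)
    means <- replicate(150, {
      lab <- sample(rep(c("positive", "negative"), each = n / 2))
      mean(fscore(matrix_fixture(x, lab)))
    })
  })
  # E[F(1, n-2)] = (n-2)/(n-4)
  expect_equal(mean(means), (n - 2) / (n - 4), tolerance = 0.05)
})

test_that("F-score TSV export carries the documented columns", {
  withr::with_seed(36, {
    x <- matrix(stats::runif(8 * 400), nrow = 8)
    fm <- matrix_fixture(x, rep(c("positive", "negative"), each = 4))
  })
  tbl <- fscore_table(fm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fscore_table(tbl, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("dipeptide", "F", "signed_norm", "rank",
                                  "mean_pos", "mean_neg"))
  expect_equal(back$F, tbl$F, tolerance = 1e-6)
})
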