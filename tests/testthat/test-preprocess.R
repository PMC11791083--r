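test_that("exclude_artifacts removes every flagged record exactly once", {
  ib <- matrix(2^rnorm(10 * 2, 25, 2), 10, 2,
               dimnames = list(NULL, c("a", "b")))
  pg <- toy_pg(ib)
  pg$meta$contaminant[1] <- TRUE
  pg$meta$reverse[2] <- TRUE
  pg$meta$site_only[3] <- TRUE
  pg$meta$contaminant[4] <- pg$meta$reverse[4] <- pg$meta$site_only[4] <- TRUE
  out <- exclude_artifacts(pg)
  expect_equal(nrow(out$ibaq), 6L)
  expect_equal(attr(out, "n_removed"), 4L)
  clean <- toy_pg(ib)
  expect_equal(nrow(exclude_artifacts(clean)$ibaq), 10L)
  expect_equal(attr(exclude_artifacts(clean), "n_removed"), 0L)
})

test_that("log2 transform maps values and preserves missingness", {
  ib <- matrix(c(8, 1, NA, 1024), 2, 2, dimnames = list(NULL, c("a", "b")))
  m <- to_log2_matrix(toy_pg(ib))
  expect_equal(m[1, 1], 3)
  expect_equal(m[2, 1], 0)
  expect_true(is.na(m[1, 2]))
  expect_equal(m[2, 2], 10)
})

test_that("median normalization matches a hand-computed oracle", {
  # 4 proteins x 3 samples, hand-chosen values with one missing cell
  v <- matrix(c(20, 22, 24, 26,
                21, 23, 25, 27,
                18, 20, NA, 24), 4, 3)
  m <- toy_matrix(v)
  nrm <- normalize_median(m)
  med <- c(median(c(20, 22, 24, 26)), median(c(21, 23, 25, 27)),
           median(c(18, 20, 24)))
  grand <- median(med)
  nf <- med - grand
  expect_equal(nrm$factors$nf, nf)
  expect_equal(nrm$grand_median, grand)
  expect_equal(unclass(nrm$matrix), unclass(m) -
                 matrix(nf, 4, 3, byrow = TRUE), ignore_attr = TRUE)
  # identical-median samples need no correction
  same <- toy_matrix(matrix(c(1, 2, 3, 1, 2, 3), 3, 2))
  expect_equal(normalize_median(same)$factors$nf, c(0, 0))
  # single sample: NF is the median of one median = 0
  one <- toy_matrix(matrix(c(5, 9), 2, 1))
  expect_equal(normalize_median(one)$factors$nf, 0)
})

test_that("normalization is idempotent and preserves within-sample differences", {
  set.seed(3)
  v <- matrix(rnorm(60 * 5, 25, 2), 60, 5)
  v <- sweep(v, 2, c(-1, 0.5, 2, 0, -0.3), `+`)
  v[sample(length(v), 40)] <- NA
  m <- toy_matrix(v)
  n1 <- normalize_median(m)
  n2 <- normalize_median(n1$matrix)
  expect_lt(max(abs(n2$factors$nf)), 1e-9)
  # within-sample differences unchanged
  d_before <- v[2, ] - v[5, ]
  d_after <- unclass(n1$matrix)[2, ] - unclass(n1$matrix)[5, ]
  expect_equal(d_after, d_before, ignore_attr = TRUE)
  # all column medians equal the grand median
  med_after <- apply(n1$matrix, 2, median, na.rm = TRUE)
  expect_lt(max(abs(med_after - n1$grand_median)), 1e-9)
})

test_that("normalization rejects a sample with no present values", {
  v <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(normalize_median(toy_matrix(v)), "zero present")
})

test_that("min-valid filter enforces k in at least one condition", {
  des <- toy_design(c("A", "B", "GFP"), 4)
  v <- matrix(NA_real_, 3, 12)
  # protein 1: 2 present per condition -> removed at k=3
  v[1, c(1, 2, 5, 6, 9, 10)] <- 25
  # protein 2: 3 present in condition A only -> retained at k=3
  v[2, 1:3] <- 25
  # protein 3: fully present
  v[3, ] <- 25
  m <- toy_matrix(v, samples = names(des$condition_of))
  out <- filter_min_valid(m, des, 3)
  expect_equal(rownames(out), c("P02", "P03"))
  expect_equal(attr(out, "removed"), "P01")
})

test_that("filters agree with an exhaustive recount oracle and are monotone in k", {
  set.seed(42)
  des <- toy_design(c("A", "B", "GFP"), 4)
  v <- matrix(rnorm(200 * 12, 25, 2), 200, 12)
  v[matrix(runif(length(v)) < 0.45, 200)] <- NA
  m <- toy_matrix(v, samples = names(des$condition_of))
  conds <- unique(des$condition_of)
  for (k in 1:4) {
    out <- filter_min_valid(m, des, k)
    # brute-force recount per protein
    keep_oracle <- vapply(seq_len(nrow(v)), function(i) {
      any(vapply(conds, function(cc) {
        sum(!is.na(v[i, des$condition_of == cc])) >= k
      }, logical(1L)))
    }, logical(1L))
    expect_equal(rownames(out), rownames(m)[keep_oracle])
  }
  # monotone: retained set shrinks as k grows
  r3 <- rownames(filter_min_valid(m, des, 3))
  r4 <- rownames(filter_min_valid(m, des, 4))
  expect_true(all(r4 %in% r3))
})

test_that("pairwise filter requires k valid bait values regardless of control", {
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(NA_real_, 2, 8)
  v[1, 1:4] <- 25          # 4 bait, 0 control -> retained
  v[2, c(1, 2, 5:8)] <- 25 # 2 bait, 4 control -> removed
  m <- toy_matrix(v, samples = names(des$condition_of))
  out <- filter_pairwise_valid(m, des, "A", "GFP", 3)
  expect_equal(rownames(out), "P01")
  expect_error(filter_pairwise_valid(m, des, "A", "A", 3), "differ")
  expect_error(filter_pairwise_valid(m, des, "A", "nope", 3), "unknown")

  # random-mask agreement with a recount oracle
  set.seed(9)
  v2 <- matrix(rnorm(150 * 8, 25, 2), 150, 8)
  v2[matrix(runif(length(v2)) < 0.5, 150)] <- NA
  m2 <- toy_matrix(v2, samples = names(des$condition_of))
  out2 <- filter_pairwise_valid(m2, des, "A", "GFP", 3)
  keep_oracle <- vapply(seq_len(nrow(v2)), function(i)
    sum(!is.na(v2[i, 1:4])) >= 3, logical(1L))
  expect_equal(rownames(out2), rownames(m2)[keep_oracle])
})
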