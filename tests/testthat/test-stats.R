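test_that("Welch statistic matches stats::t.test and the textbook formula", {
  x <- c(2.1, 2.5, 1.9, 2.3)
  y <- c(1.0, 1.2, 0.9, 1.1)
  w <- welch_statistic(x, y)
  # textbook formula, written out independently
  se <- sqrt(var(x) / 4 + var(y) / 4)
  t_o <- (mean(x) - mean(y)) / se
  df_o <- (var(x) / 4 + var(y) / 4)^2 /
    ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(w$t, t_o, tolerance = 1e-12)
  expect_equal(w$df, df_o, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_o), df_o), tolerance = 1e-12)
  # independent oracle: base R's own Welch test
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
})

test_that("Welch statistic agrees with stats::t.test on random vector pairs", {
  set.seed(21)
  for (i in 1:100) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx, sd = runif(1, 0.1, 3))
    y <- rnorm(ny, sd = runif(1, 0.1, 3), mean = rnorm(1))
    w <- welch_statistic(x, y)
    tt <- t.test(x, y)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate variances are handled as stated limits", {
  expect_equal(welch_statistic(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  z <- welch_statistic(c(2, 2), c(1, 1))
  expect_equal(z$t, Inf)
  expect_equal(z$p, 0)
  # strong separation gives a tiny p
  w <- welch_statistic(c(1, 2, 3), c(11.01, 12.005, 12.99))
  expect_lt(w$p, 1e-3)
})

test_that("s0 statistic reduces to t at s0 = 0 and shrinks with s0", {
  set.seed(4)
  x <- rnorm(4, 1); y <- rnorm(4)
  expect_identical(s0_statistic(x, y, 0), welch_statistic(x, y)$t)
  d1 <- s0_statistic(x, y, 0.1)
  d2 <- s0_statistic(x, y, 0.5)
  expect_lt(abs(d2), abs(d1))
  expect_lt(abs(d1), abs(welch_statistic(x, y)$t))
  # zero difference gives d = 0 for any s0
  expect_equal(s0_statistic(c(1, 2), c(2, 1), 0.3), 0)
  # direct formula oracle at s0 = 0.1
  x <- c(2.1, 2.5, 1.9, 2.3); y <- c(1.0, 1.2, 0.9, 1.1)
  d_o <- (mean(x) - mean(y)) / (sqrt(var(x) / 4 + var(y) / 4) + 0.1)
  expect_equal(s0_statistic(x, y, 0.1), d_o, tolerance = 1e-12)
})

test_that("permutation FDR on a 3v3 design equals direct enumeration", {
  set.seed(77)
  des <- toy_design(c("A", "GFP"), 3)
  v <- matrix(rnorm(50 * 6, 0, 1), 50, 6)
  v[1:3, 1:3] <- v[1:3, 1:3] + 5  # three strong interactors
  m <- toy_matrix(v, samples = names(des$condition_of))
  r <- permutation_fdr(m, des, "A", "GFP", s0 = 0.1, exhaustive = TRUE)
  expect_true(attr(r, "exhaustive"))
  expect_equal(attr(r, "n_permutations_used"), 9L)  # C(6,3)/2 - identity

  # independent enumeration using the scalar statistic
  splits <- combn(6, 3, simplify = FALSE)
  splits <- Filter(function(s) 1L %in% s, splits)  # halve complements
  d_for <- function(sp) vapply(seq_len(nrow(v)), function(i)
    s0_statistic(v[i, sp], v[i, -sp], 0.1), numeric(1L))
  d_obs <- d_for(1:3)
  expect_equal(r$d_s0, d_obs, tolerance = 1e-10)
  null_d <- lapply(Filter(function(s) !identical(s, 1:3), splits), d_for)
  cutoffs <- sort(unique(abs(d_obs)), decreasing = TRUE)
  fdr_o <- vapply(cutoffs, function(cc) {
    V <- mean(vapply(null_d, function(d) sum(abs(d) >= cc), numeric(1L)))
    V / max(sum(abs(d_obs) >= cc), 1)
  }, numeric(1L))
  ok <- which(fdr_o < 0.05)
  cut_o <- if (length(ok)) cutoffs[max(ok)] else Inf
  expect_equal(attr(r, "cutoff"), cut_o, tolerance = 1e-12)
  expect_equal(r$significant, abs(d_obs) >= cut_o)
})

test_that("identity permutation reproduces the observed statistic", {
  set.seed(5)
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(rnorm(30 * 8), 30, 8)
  m <- toy_matrix(v, samples = names(des$condition_of))
  r <- permutation_fdr(m, des, "A", "GFP")
  d_scalar <- vapply(seq_len(30), function(i)
    s0_statistic(v[i, 1:4], v[i, 5:8], 0.1), numeric(1L))
  expect_equal(r$d_s0, d_scalar, tolerance = 1e-10)
})

test_that("an extreme spiked protein is always called significant", {
  set.seed(6)
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(rnorm(200 * 8, 0, 0.5), 200, 8)
  v[1, 1:4] <- v[1, 1:4] + 6
  m <- toy_matrix(v, samples = names(des$condition_of))
  r <- permutation_fdr(m, des, "A", "GFP", s0 = 0.1)
  expect_true(r$significant[1])
  expect_gt(r$diff[1], 4)
})

test_that("the FDR curve is monotone along the ranked cutoffs", {
  set.seed(8)
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(rnorm(100 * 8), 100, 8)
  v[1:5, 1:4] <- v[1:5, 1:4] + 4
  m <- toy_matrix(v, samples = names(des$condition_of))
  r <- permutation_fdr(m, des, "A", "GFP")
  curve <- attr(r, "fdr_curve")
  # cutoffs descend, R ascends; V/R at the top cutoff is the smallest
  expect_true(all(diff(curve$cutoff) < 0))
  expect_true(all(diff(curve$R) > 0))
  expect_true(all(diff(curve$V) >= 0))
})

test_that("p-values are uniform under the global null", {
  set.seed(10)
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(rnorm(5000 * 8), 5000, 8)
  m <- toy_matrix(v, samples = names(des$condition_of))
  r <- permutation_fdr(m, des, "A", "GFP")
  ks <- suppressWarnings(ks.test(r$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("sampled permutations are seeded and reproducible", {
  set.seed(12)
  des <- toy_design(c("A", "GFP"), 6)  # C(12,6)/2 = 462 > 250
  v <- matrix(rnorm(80 * 12), 80, 12)
  m <- toy_matrix(v, samples = names(des$condition_of))
  r1 <- permutation_fdr(m, des, "A", "GFP", n_permutations = 100, seed = 3)
  r2 <- permutation_fdr(m, des, "A", "GFP", n_permutations = 100, seed = 3)
  expect_false(attr(r1, "exhaustive"))
  expect_equal(attr(r1, "n_permutations_used"), 100L)
  expect_identical(attr(r1, "fdr_curve"), attr(r2, "fdr_curve"))
})

test_that("degenerate designs are rejected", {
  des <- toy_design(c("A", "GFP"), 4)
  v <- matrix(rnorm(10 * 8), 10, 8)
  v[1, 1] <- NA
  m <- toy_matrix(v, samples = names(des$condition_of))
  expect_error(permutation_fdr(m, des, "A", "GFP"), "impute")
})
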