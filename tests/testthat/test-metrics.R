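# Concordance statistics against independent oracles.

test_that("dice handles identity, disjointness and partial overlap", {
  m <- array(FALSE, c(5, 5, 4))
  a <- m; a[1:4, , ] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- m; b[5, , ] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50 -> 0.5
  a2 <- array(c(rep(TRUE, 100), rep(FALSE, 100)), c(10, 10, 2))
  b2 <- array(c(rep(FALSE, 50), rep(TRUE, 100), rep(FALSE, 50)),
              c(10, 10, 2))
  expect_equal(sum(a2), 100); expect_equal(sum(b2), 100)
  expect_equal(sum(a2 & b2), 50)
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(m, m), 1)  # both empty by convention
  expect_error(dice(a, array(FALSE, c(4, 4, 4))), "same grid")
})

test_that("surface distance obeys identity, symmetry, and the radial gap", {
  a <- extract_surface(ball_volume(0.5, 10), "endo")
  b <- extract_surface(ball_volume(0.5, 12, margin = 2), "endo")
  expect_equal(max_surface_distance(a, a), 0)
  expect_equal(max_surface_distance(a, b), max_surface_distance(b, a))
  expect_equal(max_surface_distance(a, b), 2, tolerance = 0.08)
})

test_that("ICC(2,1) matches a two-way ANOVA oracle", {
  # perfect agreement
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc_2_1(m), 1)
  # absolute-agreement penalty for a constant offset
  m2 <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_lt(icc_2_1(m2), 1)

  aov_icc <- function(mat) {
    n <- nrow(mat); k <- ncol(mat)
    df <- data.frame(y = as.vector(mat),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  m3 <- cbind(c(9, 6, 8, 7), c(2, 1, 4, 1))
  expect_equal(icc_2_1(m3), aov_icc(m3), tolerance = 1e-10)
  set.seed(11)
  for (i in 1:5) {
    mm <- matrix(sample(0:9, 18, replace = TRUE), ncol = 3)
    expect_equal(icc_2_1(mm), aov_icc(mm), tolerance = 1e-10)
  }
  expect_warning(icc_2_1(matrix(5, 4, 2)), "zero variance")
  expect_error(icc_2_1(matrix(1:4, 2, 2)), "at least 3")
})

test_that("pearson_r matches the covariance formula and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2, 1, 4, 3, 7)
  res <- pearson_r(x, y)
  oracle_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, oracle_r, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_warning(pearson_r(rep(1, 5), y), "constant")
})

test_that("mann_whitney_u matches exact enumeration and wilcox.test", {
  # identical value multisets: U = n1 n2 / 2 by symmetry of midranks
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$U, 4.5)
  # complete separation
  expect_true(mann_whitney_u(c(1, 2), c(5, 6))$U %in% c(0, 4))
  expect_true(mann_whitney_u(c(5, 6), c(1, 2))$U %in% c(0, 4))
  # exact case against wilcox.test (independent implementation)
  g1 <- c(1, 3, 5); g2 <- c(2, 4)
  res <- mann_whitney_u(g1, g2)
  wt <- wilcox.test(g1, g2, exact = TRUE)
  expect_equal(res$U, unname(wt$statistic))
  expect_equal(res$p, wt$p.value, tolerance = 1e-10)
  expect_match(res$method, "exact")
  # larger seeded samples: U equals the wilcox.test statistic; the normal
  # approximation agrees closely
  set.seed(13)
  a <- rnorm(20); b <- rnorm(15, 0.8)
  res2 <- mann_whitney_u(a, b)
  wt2 <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res2$U, unname(wt2$statistic))
  expect_equal(res2$p, wt2$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("threshold sweep finds the planted signal threshold", {
  taus <- seq(0.1, 1, by = 0.1)
  set.seed(21)
  n <- 12
  areas <- t(apply(matrix(runif(n * 10, 0.5, 2), n), 1, cumsum))
  colnames(areas) <- taus
  # outcome exactly proportional to the tau = 0.2 column
  res <- threshold_sweep_correlation(areas, 3 * areas[, 2])
  expect_equal(res$best_threshold, 0.2)
  expect_equal(res$profile$r[2], 1)
  # independent outcome: no crash, finite profile
  res0 <- threshold_sweep_correlation(areas, sample(areas[, 2]))
  expect_true(all(is.finite(res0$profile$r)))

  # seeded replicates: outcome = a * area(0.3) + noise; the argmax
  # threshold lands within +-0.1 of 0.3 in at least 90% of replicates
  hits <- 0L
  for (rep_i in 1:100) {
    set.seed(1000 + rep_i)
    ar <- t(apply(matrix(runif(n * 10, 0.5, 2), n), 1, cumsum))
    colnames(ar) <- taus
    outc <- 2 * ar[, 3] + rnorm(n, sd = 0.3)
    best <- threshold_sweep_correlation(ar, outc)$best_threshold
    if (abs(best - 0.3) <= 0.1 + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("map concordance of a map with itself is perfect", {
  ph <- small_annulus(f = 0.5)
  field <- solve_laplace(ph$labels)
  epi <- extract_surface(ph$labels, "epi")
  map <- transmurality_map(trace_correspondences(field, epi, ph$labels))
  cc <- map_concordance(map, epi, map, epi)
  expect_equal(cc$icc, 1, tolerance = 1e-12)
  expect_equal(cc$r, 1, tolerance = 1e-12)
})
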