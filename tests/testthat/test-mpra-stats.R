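test_that("log_skew evaluates the alt-over-ref log2 odds ratio", {
  expect_equal(log_skew(c(10, 10, 10, 10), pseudocount = 0), 0)
  expect_equal(log_skew(c(10, 10, 30, 10), pseudocount = 0), log2(3))
  expect_error(log_skew(c(0, 0, 0, 0)), "empty table")
  # vectorized over an mpra_counts table
  counts <- make_counts_df(list("v1", "GM", 10, 10, 30, 10),
                           list("v2", "GM", 20, 10, 10, 10))
  expect_equal(log_skew(counts, pseudocount = 0), c(log2(3), log2(0.5)))
})

test_that("log_skew is antisymmetric and vodds swap-invariant (property)", {
  set.seed(21)
  for (i in 1:50) {
    tab <- rpois(4, lambda = sample(5:200, 1)) + 1
    swapped <- tab[c(3, 4, 1, 2)]
    expect_equal(log_skew(swapped, pseudocount = 0.5),
                 -log_skew(tab, pseudocount = 0.5))
    expect_equal(vodds(swapped, pseudocount = 0.5), vodds(tab, pseudocount = 0.5))
  }
})

test_that("vodds matches the closed form and is decreasing in each count", {
  expect_equal(vodds(c(4, 4, 4, 4), pseudocount = 0), 1)
  expect_equal(vodds(c(1, 1, 1, 1), pseudocount = 0), 2)
  expect_equal(vodds(c(100, 100, 100, 100), pseudocount = 0), 0.2)
  expect_error(vodds(c(0, 5, 5, 5), pseudocount = 0), "zero count")
  base <- vodds(c(20, 30, 40, 50), pseudocount = 0)
  for (j in 1:4) {
    bumped <- c(20, 30, 40, 50); bumped[j] <- bumped[j] + 10
    expect_lt(vodds(bumped, pseudocount = 0), base)
  }
})

test_that("vodds agrees with the Monte-Carlo SD of resampled log-odds", {
  # delta-method oracle: resample each cell as Poisson, recompute log odds
  set.seed(31)
  for (tab in list(c(100, 100, 100, 100), c(50, 80, 120, 60), c(30, 40, 20, 55))) {
    draws <- matrix(rpois(4 * 20000, rep(tab, each = 20000)), ncol = 4)
    draws <- draws[rowSums(draws == 0) == 0, , drop = FALSE]
    lo <- log(draws[, 3] / draws[, 4]) - log(draws[, 1] / draws[, 2])
    expect_equal(vodds(tab, pseudocount = 0), sd(lo), tolerance = 0.1)
  }
})

test_that("call_activity applies a strict fold-change rule per allele", {
  counts <- make_counts_df(list("v1", "GM", 30, 10, 10, 10))
  act <- call_activity(counts, mode = "fold_change", fc_cutoff = 1.5)
  ref_row <- act[act$allele == "ref", ]
  alt_row <- act[act$allele == "alt", ]
  expect_true(ref_row$active); expect_equal(ref_row$fold_change, 3)
  expect_false(alt_row$active); expect_equal(alt_row$fold_change, 1)
  # boundary: strictly greater than the cutoff
  bd <- call_activity(make_counts_df(list("v", "GM", 16, 10, 15, 10)),
                      mode = "fold_change", fc_cutoff = 1.5)
  expect_true(bd$active[bd$allele == "ref"])    # 1.6 > 1.5
  expect_false(bd$active[bd$allele == "alt"])   # 1.5 is not > 1.5
  expect_error(call_activity(counts, alpha = 1.2, mode = "count_test"), "alpha")
})

test_that("count_test mode gates activity on a two-sided count-ratio test", {
  strong <- make_counts_df(list("v1", "GM", 300, 100, 100, 100))
  act <- call_activity(strong, mode = "count_test", fc_cutoff = 1.5, alpha = 0.05)
  expect_true(act$active[act$allele == "ref"])
  expect_false(act$active[act$allele == "alt"])
  # large fold change on tiny counts is not significant
  tiny <- make_counts_df(list("v2", "GM", 4, 1, 1, 1))
  act2 <- call_activity(tiny, mode = "count_test", fc_cutoff = 1.5, alpha = 0.05)
  expect_false(act2$active[act2$allele == "ref"])
})

test_that("emVAR labels combine the skew filter with significance", {
  lab <- label_emvar(c(0.60, 0.0, -0.9), c(TRUE, TRUE, FALSE))
  expect_equal(lab$is_emvar, c(TRUE, FALSE, FALSE))
  expect_equal(lab$passes_skew_filter, c(TRUE, FALSE, TRUE))
  # the default threshold is a 1.5-fold skew on the log2 scale: 0.5849...
  expect_equal(floor(abs(log2(1.5)) * 1e4) / 1e4, 0.5849)
  expect_false(label_emvar(0.58, TRUE)$is_emvar)
  expect_true(label_emvar(0.59, TRUE)$is_emvar)
})

test_that("modifier labels take the top and bottom quartiles, ties inward", {
  ml <- modifier_labels(setNames(as.numeric(1:100), paste0("v", 1:100)))
  counts <- attr(ml, "counts")
  expect_equal(unname(counts["low"]), 25)
  expect_equal(unname(counts["high"]), 25)
  expect_equal(unname(counts["excluded"]), 50)
  expect_true(all(ml$vodds[ml$klass == "high"] > max(ml$vodds[ml$klass == "excluded"])))

  # ties exactly at the boundary are labeled inward (into high)
  x <- c(1, 2, 3, 4, 5, 6, 6.5, 6.5)
  ml2 <- modifier_labels(x)
  upper <- quantile(x, 0.75, names = FALSE)
  expect_equal(sum(ml2$klass == "high"), sum(x >= upper))
  expect_true(all(ml2$klass[x == 6.5] == "high"))

  expect_error(modifier_labels(1:100, lower_q = 0.5, upper_q = 0.5), "lower_q < upper_q")
  expect_error(modifier_labels(rep(1, 10)), "degenerate")
  expect_error(modifier_labels(1:5), "at least 8")
})

test_that("labeled fraction matches the quantile band (property)", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    qs <- sort(runif(2, 0.1, 0.9)); if (diff(qs) < 0.05) next
    x <- rnorm(n)
    ml <- modifier_labels(x, lower_q = qs[1], upper_q = qs[2])
    frac <- mean(ml$klass != "excluded")
    expect_lte(abs(frac - (1 - (qs[2] - qs[1]))) * n, 2 + 1e-9)
  }
})

test_that("pca_vodds returns centered loadings and explained variance", {
  set.seed(51)
  base <- rnorm(30)
  m <- rbind(gm_a = base, gm_b = base, hep = 3 * base + rnorm(30, 0, 0.1))
  p <- pca_vodds(m)
  # identical cell rows get identical first-PC loadings
  expect_equal(p$loadings["gm_a", 1], p$loadings["gm_b", 1], tolerance = 1e-10)
  expect_equal(sum(p$explained_variance), 1)
  # eigendecomposition oracle: PC variances match eigenvalues of the
  # covariance of the centered variants x cells matrix
  cen <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cen) / (nrow(cen) - 1))$values
  expect_equal(p$explained_variance, ev / sum(ev), tolerance = 1e-8)
  expect_error(pca_vodds(m[1, , drop = FALSE]), "at least 2")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(pca_vodds(m_na), "missing")
})
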