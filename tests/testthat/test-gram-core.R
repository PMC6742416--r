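make_separable_design <- function(n = 120, p = 5, seed = 81) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("TF", 1:p)))
  y <- X[, 1] > 0
  list(X = X, y = y)
}

test_that("step 1 fits a probability-valued activity classifier", {
  d <- make_separable_design()
  f1 <- fit_step1(d$X, d$y, n_trees = 200, seed = 1)
  u <- predict_U(f1, d$X)
  expect_true(all(u >= 0 & u <= 1))
  # separable design: training AUROC is 1
  expect_equal(auroc(u, d$y), 1.0)
  expect_gt(predict_U(f1, d$X[which(d$y)[1], ]), 0.9)
  # determinism under the seed
  f1b <- fit_step1(d$X, d$y, n_trees = 200, seed = 1)
  expect_identical(u, predict_U(f1b, d$X))
  expect_error(fit_step1(d$X, rep(TRUE, nrow(d$X))), "both classes")
})

test_that("step-1 probabilities average the ensemble's per-tree estimates", {
  d <- make_separable_design(n = 60)
  f1 <- fit_step1(d$X, d$y, n_trees = 100, seed = 2)
  per_tree <- predict(f1, d$X, predict.all = TRUE, num.threads = 1)$predictions
  manual <- apply(per_tree[, which(colnames(f1$predictions) == "active"), ,
                           drop = FALSE], 1, mean)
  expect_equal(unname(predict_U(f1, d$X)), unname(manual), tolerance = 1e-12)
})

test_that("shuffled labels give chance-level cross-validated step-1 AUROC", {
  set.seed(82)
  aucs <- vapply(1:10, function(s) {
    set.seed(s * 100)
    X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("TF", 1:5)))
    y <- sample(rep(c(TRUE, FALSE), each = 100))
    fold <- make_folds(paste0("r", 1:200), k = 5, seed = s)$fold
    u <- numeric(200)
    for (f in 1:5) {
      test <- which(fold == f)
      m <- fit_step1(X[-test, ], y[-test], n_trees = 100, seed = s)
      u[test] <- predict_U(m, X[test, , drop = FALSE])
    }
    auroc(u, y)
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("odds_feature matches the clipped closed form and is symmetric", {
  expect_equal(odds_feature(0.7, 0.7), 0)
  expect_equal(odds_feature(0.8, 0.5), 2)
  expect_equal(odds_feature(1.0, 0.5, eps = 1e-6),
               abs(log2((1 - 1e-6) / 1e-6)))
  expect_equal(odds_feature(1.0, 0.5, eps = 1e-6), 19.93157, tolerance = 1e-5)
  # symmetry and zero-iff-equal
  set.seed(83)
  a <- runif(50); b <- runif(50)
  expect_equal(odds_feature(a, b), odds_feature(b, a))
  expect_true(all(odds_feature(a, b)[a != b] > 0))
  expect_error(odds_feature(0.5, 0.5, eps = 0.7), "eps")
})

test_that("step 2 fits modifier classifiers on the high/low classes", {
  d <- make_separable_design(n = 100, seed = 84)
  f2 <- fit_step2(d$X, d$y, n_trees = 200, seed = 1)
  s <- predict_S(f2, d$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(auroc(s, d$y), 1.0)
  expect_error(fit_step2(d$X, rep(FALSE, nrow(d$X))), "both classes")
})

test_that("a huge penalty shrinks step 3 to the intercept-only model", {
  set.seed(85)
  n <- 400
  odds <- abs(rnorm(n)); s_b <- runif(n); s_e <- runif(n)
  y <- rbinom(n, 1, 0.3)
  fit <- fit_step3(odds, s_b, s_e, y, lambda_grid = 1e6, k = 5, seed = 1)
  expect_equal(fit$b_u, 0)
  expect_equal(fit$b_s1, 0)
  expect_equal(fit$b_s2, 0)
  prev <- mean(y)
  expect_equal(fit$b0, log(prev / (1 - prev)), tolerance = 1e-6)
})

test_that("step 3 recovers known generating coefficients at small lambda", {
  set.seed(86)
  n <- 5000
  odds <- abs(rnorm(n)); s_b <- runif(n); s_e <- runif(n)
  p <- plogis(2 * odds + 1 * s_b + 1 * s_e - 2)
  y <- rbinom(n, 1, p)
  fit <- fit_step3(odds, s_b, s_e, y, lambda_grid = 10^seq(-1, -4, length.out = 10),
                   k = 5, seed = 1)
  expect_lt(abs(fit$b_u - 2) / 2, 0.2)
  expect_lt(abs(fit$b_s1 - 1), 0.2)
  expect_lt(abs(fit$b_s2 - 1), 0.2)
  expect_lt(abs(fit$b0 - (-2)) / 2, 0.2)
})

test_that("the lasso path never regains slopes as lambda grows", {
  set.seed(87)
  n <- 600
  odds <- abs(rnorm(n)); s_b <- runif(n); s_e <- runif(n)
  y <- rbinom(n, 1, plogis(1.5 * odds - 1))
  grid <- 10^seq(0, -4, length.out = 25)
  X <- cbind(odds, s_b, s_e)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, lambda = grid)
  nonzero <- fit$df  # along decreasing lambda
  expect_true(all(diff(nonzero) >= 0))
})

test_that("duplicating every row leaves the selected model unchanged", {
  set.seed(88)
  n <- 300
  odds <- abs(rnorm(n)); s_b <- runif(n); s_e <- runif(n)
  y <- rbinom(n, 1, plogis(2 * odds - 1))
  grid <- 10^seq(-0.5, -3, length.out = 8)
  f1 <- fit_step3(odds, s_b, s_e, y, lambda_grid = grid, k = 5, seed = 1)
  f2 <- fit_step3(rep(odds, 2), rep(s_b, 2), rep(s_e, 2), rep(y, 2),
                  lambda_grid = grid, k = 5, seed = 1)
  # the per-observation-normalized objective is invariant to duplication
  expect_equal(f2$b_u, f1$b_u, tolerance = 0.1)
  expect_equal(f2$b0, f1$b0, tolerance = 0.1)
})

test_that("the literal squared-error-with-logit objective also recovers signal", {
  set.seed(89)
  n <- 800
  odds <- abs(rnorm(n)); s_b <- runif(n); s_e <- runif(n)
  y <- rbinom(n, 1, plogis(2 * odds - 1))
  fit <- fit_step3(odds, s_b, s_e, y, lambda_grid = c(1e-3, 1e-4), k = 4,
                   seed = 1, objective = "ls_logit")
  expect_gt(fit$b_u, 1)
  expect_equal(fit$objective, "ls_logit")
})

test_that("predict_gram composes the sub-calls and obeys the logistic identity", {
  tm <- tiny_trained_model()
  bundle <- tm$bundle
  ds <- tm$sim$dataset
  vids <- variant_ids(ds$bsm)[1:8]
  sc <- predict_gram(bundle, ds$bsm, ds$expression, variants = vids)
  expect_true(all(sc$M > 0 & sc$M < 1))
  # exact recomputation from the bundle's coefficients
  cf <- bundle$step3
  expect_identical(sc$M, plogis(cf$b_u * sc$odds + cf$b_s1 * sc$S_b +
                                  cf$b_s2 * sc$S_e + cf$b0))
  # hand-composed pipeline of the four sub-calls
  v <- vids[1]; cell <- rownames(ds$expression)[1]
  u_wt <- predict_U(bundle$step1, allele_feature_vector(ds$bsm, v, "ref"))
  u_mut <- predict_U(bundle$step1, allele_feature_vector(ds$bsm, v, "alt"))
  odds <- odds_feature(u_mut, u_wt, eps = bundle$eps)
  s_b <- predict_S(bundle$step2_binding, allele_feature_vector(ds$bsm, v, "ref"))
  ro <- reorder_expression(ds$bsm, v, ds$expression, sample_id = cell,
                           key_allele = bundle$key_allele)
  xe <- setNames(ro$values, paste0("rank_", seq_along(ro$values)))
  s_e <- predict_S(bundle$step2_expression, xe)
  m_hand <- plogis(cf$b_u * odds + cf$b_s1 * s_b + cf$b_s2 * s_e + cf$b0)
  row <- sc[sc$variant_id == v & sc$sample_id == cell, ]
  expect_equal(row$M, m_hand, tolerance = 1e-12)
})

test_that("an all-zero step-3 model scores everything at one half", {
  tm <- tiny_trained_model()
  null_bundle <- tm$bundle
  null_bundle$step3[c("b_u", "b_s1", "b_s2", "b0")] <- list(0, 0, 0, 0)
  sc <- predict_gram(null_bundle, tm$sim$dataset$bsm, tm$sim$dataset$expression,
                     variants = variant_ids(tm$sim$dataset$bsm)[1:5])
  expect_true(all(sc$M == 0.5))
})

test_that("M is monotone in the odds feature when its coefficient is positive", {
  tm <- tiny_trained_model()
  cf <- tm$bundle$step3
  b_u <- abs(cf$b_u) + 0.5  # force a positive slope for the check
  odds_grid <- seq(0, 10, length.out = 50)
  m <- plogis(b_u * odds_grid + cf$b_s1 * 0.5 + cf$b_s2 * 0.5 + cf$b0)
  expect_true(all(diff(m) >= 0))
})
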