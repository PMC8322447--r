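# Correlation screening, z-scoring, LASSO, nested CV, evaluation,
# contributions.

test_that("correlations match hand computation with valid intervals", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate(x, 2 * x + 1)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)
  y <- c(2, 1, 4, 3)
  expect_equal(correlate(x, y)$estimate, 0.6)
  expect_equal(correlate(x, y, "spearman")$estimate, 0.6)
  ci <- correlate(rnorm(30), rnorm(30))$ci95
  expect_length(ci, 2)
  expect_lt(ci[1], ci[2])
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("screening keeps |r| >= threshold and picks the best electrode", {
  set.seed(10)
  n <- 80
  y <- rnorm(n)
  mk <- function(r) r * y + sqrt(1 - r^2) * rnorm(n)
  tab <- data.frame(participant = 1:n,
                    a__Fz = mk(-0.1), a__Cz = mk(-0.5), a__Pz = mk(-0.45),
                    b__Fz = mk(0.05), b__Cz = mk(0.02), b__Pz = mk(0.01),
                    score = y)
  man <- data.frame(kind = rep(c("a", "b"), each = 3),
                    channel = rep(c("Fz", "Cz", "Pz"), 2),
                    column = c("a__Fz", "a__Cz", "a__Pz",
                               "b__Fz", "b__Cz", "b__Pz"))
  sel <- screen_features(tab, threshold = 0.2, manifest = man)
  expect_equal(sel$kind, "a")
  r_all <- vapply(c("a__Fz", "a__Cz", "a__Pz"),
                  function(cl) cor(tab[[cl]], y), numeric(1))
  expect_equal(sel$channel, c("Fz", "Cz", "Pz")[which.max(abs(r_all))])
  # the threshold is inclusive: screening at exactly |r| keeps the feature
  r_best <- max(abs(r_all))
  expect_equal(nrow(screen_features(tab, threshold = r_best,
                                    manifest = man)), 1)
  expect_equal(nrow(screen_features(tab, threshold = r_best + 1e-12,
                                    manifest = man)), 0)
})

test_that("z-scoring standardizes with the n-1 SD and is idempotent", {
  tab <- data.frame(participant = 1:3, f = c(1, 2, 3), score = c(5, 6, 7))
  z <- zscore_features(tab, "f")
  expect_equal(z$f, c(-1, 0, 1))
  expect_equal(zscore_features(z, "f")$f, z$f, tolerance = 1e-12)
  expect_equal(mean(z$f), 0)
  expect_error(zscore_features(data.frame(f = rep(1, 4), score = 1:4), "f"),
               "constant")
})

test_that("LASSO minimizes the stated loss: OLS limit, null model, KKT", {
  set.seed(11)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- as.numeric(X %*% c(1.5, -2, 0, 0, 1) + rnorm(50, sd = 0.5))
  m0 <- fit_lasso(X, y, 0)
  expect_equal(unname(m0$beta), unname(coef(lm(y ~ X))[-1]),
               tolerance = 1e-8)
  n <- nrow(X)
  lam_max <- max(abs(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))) / n
  mnull <- fit_lasso(X, y, lam_max * (1 + 1e-10))
  expect_true(all(mnull$beta == 0))
  expect_equal(mnull$beta0, mean(y))
  for (lam in c(0.05, 0.3, 1)) {
    m <- fit_lasso(X, y, lam)
    res <- y - m$beta0 - as.numeric(X %*% m$beta)
    grad <- as.numeric(crossprod(sweep(X, 2, colMeans(X)), res)) / n
    expect_true(all(abs(grad) <= lam + 1e-6))
    act <- m$beta != 0
    if (any(act))
      expect_equal(grad[act], lam * sign(m$beta[act]), tolerance = 1e-6,
                   ignore_attr = TRUE)
  }
})

test_that("LASSO agrees with an independent solver on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- as.numeric(X %*% rnorm(8) + rnorm(60))
    lam <- runif(1, 0.05, 1)
    m <- fit_lasso(X, y, lam)
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(unname(m$beta), as.numeric(g$beta), tolerance = 1e-6)
  }
})

test_that("active-set size is non-increasing in lambda on orthogonal designs", {
  set.seed(13)
  Q <- qr.Q(qr(matrix(rnorm(60 * 10), 60, 10)))
  y <- as.numeric(Q %*% seq(2, -2, length.out = 10) + rnorm(60, sd = 0.1))
  sizes <- vapply(seq(0, 0.05, length.out = 30), function(l)
    sum(fit_lasso(Q, y, l)$beta != 0), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("nested CV reduces to plain LOOCV on a one-lambda grid", {
  sim <- simulate_feature_table(n = 30, n_features = 6, n_informative = 3,
                                r_true = -0.5, seed = 14)
  cols <- sprintf("f%03d", 1:6)
  pr <- nested_cv_predict(sim$table, cols, lambda_grid = 0.5,
                          inner_folds = 5, seed = 1)
  tab <- zscore_features(sim$table, cols)
  manual <- vapply(1:30, function(i) {
    m <- fit_lasso(as.matrix(tab[-i, cols]), tab$score[-i], 0.5)
    predict(m, as.matrix(tab[i, cols, drop = FALSE]))
  }, numeric(1))
  expect_equal(pr$predictions$predicted, manual, tolerance = 1e-10)
  expect_true(all(pr$fold_lambda == 0.5))
})

test_that("noiseless linear scores are recovered out of fold", {
  set.seed(15)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3)
  tab <- data.frame(participant = 1:n, X,
                    score = as.numeric(X %*% c(30, -20, 10)) + 500)
  names(tab) <- c("participant", "x1", "x2", "x3", "score")
  pr <- nested_cv_predict(tab, c("x1", "x2", "x3"),
                          lambda_grid = seq(0, 5, length.out = 50),
                          inner_folds = 5, seed = 2)
  expect_lt(max(abs(pr$predictions$predicted - tab$score)), 1e-3)
  expect_equal(pr$metrics$mad_mean, 0, tolerance = 1e-4)
})

test_that("nested CV is deterministic and separates screened-out features", {
  sim <- simulate_feature_table(n = 40, n_features = 20, n_informative = 4,
                                r_true = -0.45, seed = 16)
  sel <- screen_features(sim$table, threshold = 0.2)
  pr1 <- nested_cv_predict(sim$table, sel$column,
                           lambda_grid = seq(0, 5, length.out = 40),
                           inner_folds = 10, seed = 3)
  pr2 <- nested_cv_predict(sim$table, sel$column,
                           lambda_grid = seq(0, 5, length.out = 40),
                           inner_folds = 10, seed = 3)
  expect_identical(pr1$predictions, pr2$predictions)
  expect_identical(pr1$contributions, pr2$contributions)
  # features that failed the screen never enter any model
  dropped <- setdiff(sprintf("f%03d", 1:20), sel$column)
  for (m in pr1$models) expect_false(any(dropped %in% names(m$beta)))
})

test_that("evaluation metrics and contributions follow their definitions", {
  ev <- evaluate_predictions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mad_mean, 0)
  ev2 <- evaluate_predictions(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_equal(ev2$mad_mean, 10)
  expect_equal(ev2$mad_sd, 0)
  expect_equal(ev2$pearson_r, 1)
  t4 <- c(0, 1, 2, 5); p4 <- c(1, 1, 3, 4)
  ev3 <- evaluate_predictions(t4, p4)
  expect_equal(ev3$mad_mean, mean(abs(t4 - p4)))
  expect_equal(ev3$rmse, sqrt(mean((t4 - p4)^2)))

  mk_model <- function(beta) structure(list(beta0 = 0, beta = beta,
                                            lambda = 1, n = 10,
                                            m = length(beta)),
                                       class = "lasso_model")
  expect_equal(unname(contributions(list(mk_model(c(f1 = 2, f2 = -1))))),
               c(1, 0.5))
  two <- list(mk_model(c(f1 = 2, f2 = 0)), mk_model(c(f1 = 0, f2 = 2)))
  expect_equal(unname(contributions(two)), c(1, 1))
  expect_equal(unname(contributions(list(mk_model(c(f1 = 0, f2 = 0))))),
               c(0, 0))
})

test_that("train-only z-scoring does not beat full-sample z-scoring", {
  sim <- simulate_feature_table(n = 40, n_features = 10, n_informative = 4,
                                r_true = -0.45, seed = 17)
  cols <- sprintf("f%03d", 1:10)
  grid <- seq(0, 5, length.out = 30)
  r_full <- nested_cv_predict(sim$table, cols, grid, inner_folds = 5,
                              seed = 4, zscore = "full")$metrics$pearson_r
  r_train <- nested_cv_predict(sim$table, cols, grid, inner_folds = 5,
                               seed = 4, zscore = "train")$metrics$pearson_r
  expect_lte(r_train, r_full + 0.05)
})
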