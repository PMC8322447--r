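## Score prediction: Pearson screening (|r| >= 0.2, best electrode per
## feature), z-scoring, LASSO with the loss
##   L(beta) = (1/2N) sum_i (y_i - beta0 - x_i' beta)^2 + lambda sum_j |beta_j|
## fit by cyclic coordinate descent, under outer leave-one-out and inner
## 10-fold cross-validation over 500 lambdas in [0, 5], plus evaluation and
## normalized feature contributions.

#' Correlation with confidence interval
#'
#' Pearson product-moment or Spearman rank correlation with a Fisher-z 95%
#' interval and two-sided p value.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `ci95`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(estimate = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
         p = ct$p.value, method = method, n = length(x))
  } else {
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    rho <- unname(ct$estimate)
    z <- atanh(rho); se <- 1 / sqrt(length(x) - 3)
    list(estimate = rho,
         ci95 = tanh(z + c(-1, 1) * stats::qnorm(0.975) * se),
         p = ct$p.value, method = method, n = length(x))
  }
}

#' Screen features by correlation with the score
#'
#' Pearson r against the score is computed per feature and electrode;
#' features reaching `|r| >= threshold` on at least one electrode are kept,
#' represented by the electrode with the largest `|r|` (ties go to the
#' earlier channel in `channel_order`).  Without a manifest every column is
#' its own feature.
#'
#' @param table Feature table with a `score` column.
#' @param threshold Inclusive screening threshold (default 0.2).
#' @param manifest Optional manifest (attribute `"manifest"` of the table is
#'   used when present) mapping columns to (kind, channel).
#' @param channel_order Tie-break priority for channels.
#' @param use_abs Select the electrode by `|r|` (default); `FALSE` selects
#'   by the most positive r literally.
#' @return Data frame: `kind`, `channel`, `column`, `r`, ordered as in the
#'   manifest.
#' @export
screen_features <- function(table, threshold = 0.2,
                            manifest = attr(table, "manifest"),
                            channel_order = c("Fz", "Cz", "Pz", "FC5", "FC6"),
                            use_abs = TRUE) {
  stopifnot("score" %in% names(table))
  y <- table$score
  if (is.null(manifest)) {
    cols <- setdiff(names(table), c("participant", "score"))
    manifest <- data.frame(kind = cols, channel = NA_character_,
                           column = cols, stringsAsFactors = FALSE)
  }
  out <- list()
  for (k in unique(manifest$kind)) {
    sub <- manifest[manifest$kind == k, , drop = FALSE]
    if (!all(is.na(sub$channel))) {
      pr <- order(match(sub$channel, channel_order))
      sub <- sub[pr, , drop = FALSE]
    }
    rs <- vapply(sub$column, function(cl) {
      x <- table[[cl]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    pass <- which(!is.na(rs) & abs(rs) >= threshold)
    if (!length(pass)) next
    best <- pass[which.max(if (use_abs) abs(rs[pass]) else rs[pass])]
    out[[length(out) + 1L]] <-
      data.frame(kind = k, channel = sub$channel[best],
                 column = sub$column[best], r = unname(rs[best]),
                 stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(kind = character(0), channel = character(0),
                      column = character(0), r = numeric(0)))
  do.call(rbind, out)
}

#' Median-impute missing feature values
#'
#' Replaces `NA`s in the given columns by the cohort median of the column.
#'
#' @param table Feature table.
#' @param columns Columns to impute (default: all but participant/score).
#' @return The table with imputed columns.
#' @export
impute_median <- function(table,
                          columns = setdiff(names(table),
                                            c("participant", "score"))) {
  for (cl in columns) {
    x <- table[[cl]]
    if (anyNA(x)) {
      m <- stats::median(x, na.rm = TRUE)
      x[is.na(x)] <- m
      table[[cl]] <- x
    }
  }
  table
}

#' Z-score feature columns
#'
#' Standardizes each column to mean 0, SD 1 (SD with denominator n-1) over
#' the full sample.
#'
#' @param table Feature table.
#' @param columns Columns to standardize.
#' @return The table with standardized columns.
#' @export
zscore_features <- function(table,
                            columns = setdiff(names(table),
                                              c("participant", "score"))) {
  for (cl in columns) {
    x <- table[[cl]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop("cannot z-score constant column: ", cl, call. = FALSE)
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

# Moore-Penrose least squares for the lambda = 0 case
pinv_lm <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  d <- s$d
  pos <- d > tol * max(d, 0)
  beta <- s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], y)) / d[pos])
  as.numeric(beta)
}

#' Fit the LASSO at one regularization weight
#'
#' Minimizes `(1/2N) sum (y - beta0 - x'beta)^2 + lambda sum |beta|` with an
#' unpenalized intercept: predictors and response are centered, the centered
#' problem is solved by cyclic coordinate descent with soft-thresholding
#' (convergence when the largest coefficient change falls below `tol`), and
#' `beta0 = mean(y) - colMeans(X) %*% beta`.  At `lambda = 0` the exact
#' least-squares solution is used (pseudoinverse when rank-deficient).
#'
#' @param X Numeric matrix (n x p).
#' @param y Numeric response (length n).
#' @param lambda Regularization weight (>= 0).
#' @param tol Convergence tolerance on coefficient changes.
#' @param max_sweeps Sweep cap; non-convergence is an error.
#' @return Object of class `lasso_model`: `beta0`, `beta` (named), `lambda`,
#'   `n`, `m`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-7, max_sweeps = 100000L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)",
                                 call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  if (lambda == 0) {
    beta <- pinv_lm(Xc, yc)
  } else {
    fit <- .lasso_cd(Xc, yc, lambda, rep(0, ncol(X)), tol,
                     as.integer(max_sweeps))
    if (!fit$converged)
      stop("coordinate descent did not converge (lambda = ", lambda,
           ", p = ", ncol(X), ", max change above ", tol, " after ",
           max_sweeps, " sweeps)", call. = FALSE)
    beta <- fit$beta
  }
  names(beta) <- colnames(X)
  structure(list(beta0 = ym - sum(xm * beta), beta = beta, lambda = lambda,
                 n = nrow(X), m = ncol(X)),
            class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$beta + object$beta0)
}

# warm-started path over a descending lambda grid on centered data;
# returns p x nlambda coefficients (original scale, centered problem)
lasso_path <- function(Xc, yc, lambdas_desc, tol = 1e-7,
                       max_sweeps = 100000L) {
  pos <- lambdas_desc > 0
  B <- matrix(0, ncol(Xc), length(lambdas_desc))
  if (any(pos)) {
    fit <- .lasso_path_cd(Xc, yc, lambdas_desc[pos], tol,
                          as.integer(max_sweeps))
    if (!all(fit$converged))
      stop("coordinate descent did not converge along the path",
           call. = FALSE)
    B[, pos] <- fit$beta
  }
  if (any(!pos)) B[, !pos] <- pinv_lm(Xc, yc)
  B
}

#' Predict scores by LASSO under nested cross-validation
#'
#' Outer loop: leave one participant out.  Inner loop on the training
#' remainder: 10-fold cross-validation scores every candidate lambda (500
#' evenly spaced values in `[0, 5]` by default) by pooled RMSE; the
#' minimum-RMSE lambda (ties to the smaller lambda) is refit on the full
#' training split and the held-out participant is predicted.  Feature
#' z-scoring is done once on the full sample by default (`zscore = "full"`,
#' replicating the original procedure, which leaks test information into
#' the scaling); `zscore = "train"` recomputes means/SDs on each training
#' split.  Missing feature values are median-imputed first.
#'
#' @param table Feature table with a `score` column.
#' @param columns Feature columns to use (e.g. `screen_features()$column`).
#' @param lambda_grid Candidate lambdas.
#' @param inner_folds Number of inner folds.
#' @param seed Integer seed; fold assignment is a deterministic shuffle
#'   derived from it.
#' @param zscore `"full"` or `"train"`.
#' @param tol,max_sweeps Coordinate-descent controls.
#' @return Object of class `prediction_result`: `predictions` (data frame
#'   with `participant`, `true`, `predicted`), `metrics` (see
#'   [evaluate_predictions()]), `fold_lambda`, `fold_train_rmse`, `models`,
#'   `contributions`.
#' @export
nested_cv_predict <- function(table, columns,
                              lambda_grid = seq(0, 5, length.out = 500),
                              inner_folds = 10, seed = 1L,
                              zscore = c("full", "train"),
                              tol = 1e-7, max_sweeps = 100000L) {
  zscore <- match.arg(zscore)
  stopifnot("score" %in% names(table), all(columns %in% names(table)))
  n <- nrow(table)
  if (n < inner_folds + 1)
    stop("need at least inner_folds + 1 participants", call. = FALSE)
  table <- impute_median(table, columns)
  if (zscore == "full") table <- zscore_features(table, columns)
  y <- table$score
  X <- as.matrix(table[, columns, drop = FALSE])
  ord <- order(lambda_grid, decreasing = TRUE)   # descending for warm starts
  lam_desc <- lambda_grid[ord]
  preds <- numeric(n)
  fold_lambda <- numeric(n); fold_rmse <- numeric(n)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[i, , drop = FALSE]
    if (zscore == "train") {
      mu <- colMeans(Xtr); sg <- apply(Xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    set.seed(seed + i)
    fold <- sample(rep_len(seq_len(inner_folds), length(tr)))
    sse <- numeric(length(lam_desc)); cnt <- 0L
    for (f in seq_len(inner_folds)) {
      hold <- fold == f
      xm <- colMeans(Xtr[!hold, , drop = FALSE])
      ym <- mean(ytr[!hold])
      Xc <- sweep(Xtr[!hold, , drop = FALSE], 2, xm)
      B <- lasso_path(Xc, ytr[!hold] - ym, lam_desc, tol, max_sweeps)
      Xh <- sweep(Xtr[hold, , drop = FALSE], 2, xm)
      P <- Xh %*% B + ym                      # n_hold x nlambda
      sse <- sse + colSums((P - ytr[hold])^2)
      cnt <- cnt + sum(hold)
    }
    rmse <- sqrt(sse / cnt)
    # min RMSE; ties -> smaller lambda (grid is descending here)
    best_rmse <- min(rmse)
    cand <- which(rmse <= best_rmse)
    best <- cand[which.min(lam_desc[cand])]
    lam_star <- lam_desc[best]
    model <- fit_lasso(Xtr, ytr, lam_star, tol, max_sweeps)
    preds[i] <- predict(model, Xte)
    fold_lambda[i] <- lam_star
    fold_rmse[i] <- sqrt(mean((predict(model, Xtr) - ytr)^2))
    models[[i]] <- model
  }
  res <- list(predictions = data.frame(participant = table$participant %||%
                                         seq_len(n),
                                       true = y, predicted = preds),
              metrics = evaluate_predictions(y, preds),
              fold_lambda = fold_lambda, fold_train_rmse = fold_rmse,
              models = models,
              contributions = contributions(models))
  class(res) <- "prediction_result"
  res
}

#' @export
print.prediction_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<prediction_result> n = %d: r = %.3f (95%% CI %.3f..%.3f), MAD = %.1f +/- %.1f, RMSE = %.1f\n",
              nrow(x$predictions), m$pearson_r, m$ci95[1], m$ci95[2],
              m$mad_mean, m$mad_sd, m$rmse))
  invisible(x)
}

#' Evaluate predicted against true scores
#'
#' @param true,predicted Equal-length numeric vectors.
#' @return List: `pearson_r`, `ci95`, `p`, `mad_mean`, `mad_sd` (mean and SD
#'   of the absolute differences), `rmse`.
#' @export
evaluate_predictions <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  ad <- abs(true - predicted)
  ct <- correlate(true, predicted, "pearson")
  list(pearson_r = ct$estimate, ci95 = ct$ci95, p = ct$p,
       mad_mean = mean(ad), mad_sd = stats::sd(ad),
       rmse = sqrt(mean(ad^2)))
}

#' Normalized feature contributions
#'
#' Coefficients of each feature are averaged across all (outer-fold) models,
#' absolute values taken, and divided by the maximum so contributions lie in
#' `[0, 1]`; features never selected get 0.  If every coefficient is zero
#' the normalization is skipped and all contributions are 0.
#'
#' @param models List of [fit_lasso()] models sharing the feature set.
#' @return Named numeric vector in `[0, 1]`.
#' @export
contributions <- function(models) {
  stopifnot(length(models) >= 1)
  B <- vapply(models, function(m) m$beta, numeric(length(models[[1]]$beta)))
  avg <- abs(rowMeans(matrix(B, nrow = length(models[[1]]$beta))))
  names(avg) <- names(models[[1]]$beta)
  mx <- max(avg)
  if (mx > 0) avg / mx else avg
}
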