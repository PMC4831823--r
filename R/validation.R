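#' k-fold cross-validation of a rational-polynomial fit
#'
#' Randomly partitions the assessable records (everything except the
#' conception anchors) into `k` folds. Each fold in turn is held out: the
#' model is fitted to the remaining folds plus all anchors, and the mean
#' squared sqrt-scale residual is computed on both the training records
#' and the held-out fold. Anchors are pinned to the training side because
#' they are constraints rather than measurements; testing on a forced
#' point would distort the error estimate.
#'
#' @param data an augmented [ib_data] object.
#' @param degrees degree pair passed to [ratpoly()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the random partition.
#' @param refine passed to [ratpoly()].
#' @return an object of class `ratpoly_cv`: list with `k`, `per_fold`
#'   (data frame of train/test msr), `mean_train_msr`, `mean_test_msr`,
#'   `fold` (fold id per assessable record), `seed`.
#' @export
cv_ratpoly <- function(data, degrees = c(3, 4), k = 5, seed, refine = TRUE) {
  stopifnot(inherits(data, "ib_data"))
  if (missing(seed)) stop("'seed' is required")
  if (k < 2) stop("k must be >= 2")
  idx_assess <- which(is_assessable(data))
  idx_anchor <- which(!is_assessable(data))
  n <- length(idx_assess)
  p <- sum(degrees) + 1L
  if (floor(n / k) < 2L) stop("folds too small")
  if (n - ceiling(n / k) < p + 2L) stop("fold too small to fit degrees")

  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  per <- data.frame(fold = seq_len(k), train_msr = NA_real_,
                    test_msr = NA_real_, n_test = NA_integer_)
  for (f in seq_len(k)) {
    test_idx <- idx_assess[fold == f]
    train_idx <- c(idx_assess[fold != f], idx_anchor)
    train <- data[train_idx, , drop = FALSE]
    fit <- suppressWarnings(
      ratpoly_fit_engine(train$age_years,
                         sqrt_transform(train$inhibin_pg_ml),
                         degrees[1L], degrees[2L], refine = refine,
                         assess = is_assessable(train)))
    mu_train <- rp_eval_model(fit, data$age_years[idx_assess[fold != f]])
    mu_test <- rp_eval_model(fit, data$age_years[test_idx])
    y_train <- sqrt_transform(data$inhibin_pg_ml[idx_assess[fold != f]])
    y_test <- sqrt_transform(data$inhibin_pg_ml[test_idx])
    per$train_msr[f] <- mean((y_train - mu_train)^2)
    per$test_msr[f] <- mean((y_test - mu_test)^2)
    per$n_test[f] <- length(test_idx)
  }
  out <- list(k = k, per_fold = per,
              mean_train_msr = mean(per$train_msr),
              mean_test_msr = mean(per$test_msr),
              fold = fold, assess_index = idx_assess, seed = seed,
              degrees = degrees)
  class(out) <- "ratpoly_cv"
  out
}

#' @export
print.ratpoly_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, degrees (%d, %d), seed %d\n",
              x$k, x$degrees[1L], x$degrees[2L], x$seed))
  print(transform(x$per_fold, train_msr = round(train_msr, 3),
                  test_msr = round(test_msr, 3)), row.names = FALSE)
  cat(sprintf("mean train msr %.3f, mean test msr %.3f (sqrt scale)\n",
              x$mean_train_msr, x$mean_test_msr))
  invisible(x)
}

#' Bootstrap estimate of extra-sample prediction error
#'
#' Repeatedly resamples the assessable records with replacement (same
#' size), refits the model on each bootstrap sample (anchors always
#' included as constraints), and records the mean squared sqrt-scale
#' residual of the bootstrap sample. The extra-sample prediction error
#' estimate is the mean of those bootstrap mean squared errors. An
#' out-of-bag variant - scoring each fit on the records left out of its
#' resample - is available but is not the default.
#'
#' Degenerate resamples (too few distinct ages to fit) are retried; the
#' retry count is reported.
#'
#' @param data an augmented [ib_data] object.
#' @param degrees degree pair passed to [ratpoly()].
#' @param iterations number of bootstrap iterations (default 2000).
#' @param seed integer seed.
#' @param refine passed to [ratpoly()].
#' @param out_of_bag score on out-of-bag records instead of the bootstrap
#'   sample itself.
#' @return an object of class `ratpoly_boot`: list with
#'   `bootstrap_msrs`, `extra_sample_error`, `iterations`, `retries`,
#'   `seed`.
#' @export
bootstrap_ratpoly <- function(data, degrees = c(3, 4), iterations = 2000,
                              seed, refine = TRUE, out_of_bag = FALSE) {
  stopifnot(inherits(data, "ib_data"))
  if (missing(seed)) stop("'seed' is required")
  if (iterations < 1) stop("iterations must be >= 1")
  idx_assess <- which(is_assessable(data))
  idx_anchor <- which(!is_assessable(data))
  n <- length(idx_assess)
  p <- sum(degrees) + 1L
  age <- data$age_years
  ysq <- sqrt_transform(data$inhibin_pg_ml)

  msrs <- numeric(iterations)
  retries <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      repeat {
        take <- sample(idx_assess, n, replace = TRUE)
        if (length(unique(age[take])) >= p) break
        retries <- retries + 1L
        if (retries > 100L * iterations) stop("degenerate resampling")
      }
      fit_idx <- c(take, idx_anchor)
      fit <- tryCatch(suppressWarnings(
        ratpoly_fit_engine(age[fit_idx], ysq[fit_idx],
                           degrees[1L], degrees[2L], refine = refine)),
        error = function(e) NULL)
      if (is.null(fit)) {
        retries <- retries + 1L
        if (retries > 100L * iterations) stop("degenerate resampling")
        msrs[it] <- NA_real_
        next
      }
      score_idx <- if (out_of_bag) setdiff(idx_assess, take) else take
      mu <- rp_eval_model(fit, age[score_idx])
      msrs[it] <- mean((ysq[score_idx] - mu)^2)
    }
  })
  msrs <- msrs[is.finite(msrs)]
  out <- list(iterations = iterations, bootstrap_msrs = msrs,
              extra_sample_error = mean(msrs), retries = retries,
              seed = seed, degrees = degrees, out_of_bag = out_of_bag)
  class(out) <- "ratpoly_boot"
  out
}

#' @export
print.ratpoly_boot <- function(x, ...) {
  cat(sprintf(
    "bootstrap (%d iterations%s, seed %d): extra-sample error %.3f (sqrt scale)\n",
    x$iterations, if (x$out_of_bag) ", out-of-bag" else "", x$seed,
    x$extra_sample_error))
  if (x$retries > 0L) cat(sprintf("  degenerate resamples retried: %d\n",
                                  x$retries))
  invisible(x)
}

# direct curve evaluation for internal scoring: unlike predict(), this
# does not refuse a non-positive denominator -- a degenerate fold or
# resample fit simply scores badly, which is the honest outcome
rp_eval_model <- function(fit, ages) {
  rp_eval_theta(fit$coefficients, ages, fit$degrees[["num"]],
                fit$degrees[["den"]])$value
}
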