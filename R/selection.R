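#' Residual-normality agreement
#'
#' Quantifies how closely a residual histogram matches an idealised
#' Gaussian. Residuals are binned with the Freedman-Diaconis rule, a
#' Gaussian density with the residuals' own mean and SD is evaluated at
#' the bin midpoints, and the agreement is 100 times the r-squared of the
#' least-squares correspondence between observed and Gaussian bin heights,
#' floored at 0.
#'
#' The binning rule and the definition are stated here because "percent
#' agreement with a perfect Gaussian" has no unique convention; this one
#' is deterministic and reproducible.
#'
#' @param residuals numeric vector, at least 30 values.
#' @return agreement in percent (0-100).
#' @export
residual_normality <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 30L) stop("need at least 30 residuals")
  brk <- grDevices::nclass.FD(residuals)
  h <- graphics::hist(residuals, breaks = brk, plot = FALSE)
  obs <- h$density
  mu <- mean(residuals); s <- stats::sd(residuals)
  gau <- stats::dnorm(h$mids, mu, s)
  ssr <- sum((obs - gau)^2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(0)
  max(0, 100 * (1 - ssr / sst))
}

#' Non-negativity check between conception and birth
#'
#' Scans the sqrt-scale mean curve on a dense grid over the given age
#' range (by default conception to birth) and flags a violation if the
#' curve drops materially below zero, i.e. if the model implies negative
#' inhibin B levels in utero. The tolerance (default 0.1 on the sqrt
#' scale, about 0.01 pg/mL) exists because curves forced through the
#' conception anchor legitimately pass within rounding distance of zero
#' at the anchor itself.
#'
#' @param model a `ratpoly` model.
#' @param age_range ages to scan, default `c(-0.75, 0)`.
#' @param tol sqrt-scale tolerance below zero that still counts as "zero".
#' @param n_grid grid resolution.
#' @return list with `violation` (flag), `offending_ages`, and
#'   `min_value` (sqrt scale).
#' @export
check_nonnegativity <- function(model, age_range = c(-0.75, 0), tol = 0.1,
                                n_grid = 1501L) {
  stopifnot(inherits(model, "ratpoly"))
  g <- seq(age_range[1L], age_range[2L], length.out = n_grid)
  m <- model$degrees[["num"]]; n <- model$degrees[["den"]]
  e <- rp_eval_theta(model$coefficients, g, m, n)
  v <- e$value
  v[e$den == 0] <- -Inf
  # a denominator sign change makes the curve swing negative as well
  bad <- v < -tol | e$den < 0
  list(violation = any(bad),
       offending_ages = g[bad],
       min_value = min(v))
}

#' Enumerate candidate degrees and select a model
#'
#' Fits every (numerator degree, denominator degree) pair on the grid,
#' scores each candidate by r-squared, mean squared residual and residual
#' normality (anchors excluded from assessment), and applies the
#' acceptance rules: candidates whose curve goes negative between
#' conception and birth, or whose denominator has a root inside the data
#' age range, are rejected; candidates with r-squared more than 10%
#' (relative) below the best admissible one are flagged as underfit; among
#' admissible, non-underfit candidates the one with fewest parameters is
#' selected, ties broken by higher residual normality, then higher
#' r-squared. The procedure is deterministic given the data and invariant
#' to the enumeration order of the grid.
#'
#' @param data an [ib_data] object (typically augmented with anchors and
#'   imputed adult records).
#' @param num_degrees,den_degrees integer vectors spanning the grid
#'   (default 0-5 each, 36 candidates).
#' @param refine passed to [ratpoly()].
#' @param underfit_factor relative r-squared factor defining underfit
#'   (default 0.9, i.e. "more than 10% lower").
#' @param neg_tol tolerance for [check_nonnegativity()].
#' @param conception_age lower end of the non-negativity scan.
#' @return an object of class `ratpoly_selection`: a data frame of
#'   candidate scores (one row per candidate) with the fitted models in
#'   `attr(, "models")` and the selected model in `attr(, "selected")`.
#' @export
select_ratpoly <- function(data, num_degrees = 0:5, den_degrees = 0:5,
                           refine = TRUE, underfit_factor = 0.9,
                           neg_tol = 0.1, conception_age = -0.75) {
  stopifnot(inherits(data, "ib_data"))
  grid <- expand.grid(num = as.integer(num_degrees),
                      den = as.integer(den_degrees))
  if (nrow(grid) == 0L) stop("empty degree grid")

  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- grid$num[i]; n <- grid$den[i]
    fit <- tryCatch(suppressWarnings(
      ratpoly(data, degrees = c(m, n), refine = refine)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(num_degree = m, den_degree = n,
                              n_params = m + n + 1L, r2 = NA_real_,
                              msr = NA_real_, normality_pct = NA_real_,
                              negativity_violation = NA, den_ok = NA,
                              failed = TRUE)
      next
    }
    neg <- check_nonnegativity(fit, age_range = c(conception_age, 0),
                               tol = neg_tol)
    d <- fit$diagnostics
    rows[[i]] <- data.frame(num_degree = m, den_degree = n,
                            n_params = m + n + 1L, r2 = d$r2, msr = d$msr,
                            normality_pct = d$normality_pct,
                            negativity_violation = neg$violation,
                            den_ok = fit$den_ok, failed = FALSE)
    models[[i]] <- fit
  }
  scores <- do.call(rbind, rows)

  admissible <- !scores$failed & !scores$negativity_violation & scores$den_ok
  if (!any(admissible)) stop("no admissible model: all candidates rejected")
  best_r2 <- max(scores$r2[admissible])
  # "more than 10% (relative) below the best": expressed via |best| so the
  # rule stays meaningful when the best admissible r2 is at or below zero
  cut <- best_r2 - (1 - underfit_factor) * abs(best_r2)
  scores$underfit <- admissible & scores$r2 < cut
  pool <- which(admissible & !scores$underfit)
  # parsimony first, then residual normality, then r2; degrees as a
  # deterministic final tie-break so enumeration order never matters
  ord <- order(scores$n_params[pool], -scores$normality_pct[pool],
               -scores$r2[pool], scores$num_degree[pool],
               scores$den_degree[pool])
  sel <- pool[ord[1L]]
  scores$selected <- seq_len(nrow(scores)) == sel
  scores <- scores[order(scores$n_params, scores$num_degree,
                         scores$den_degree), , drop = FALSE]
  rownames(scores) <- NULL
  attr(scores, "models") <- models
  attr(scores, "selected") <- models[[sel]]
  attr(scores, "selected_degrees") <- c(grid$num[sel], grid$den[sel])
  attr(scores, "binning") <- "Freedman-Diaconis"
  class(scores) <- c("ratpoly_selection", "data.frame")
  scores
}

#' @export
print.ratpoly_selection <- function(x, ...) {
  cat("Candidate rational-polynomial models (sqrt scale)\n")
  df <- as.data.frame(x)
  df$r2 <- round(df$r2, 4)
  df$msr <- round(df$msr, 3)
  df$normality_pct <- round(df$normality_pct, 1)
  print(df, row.names = FALSE)
  sd <- attr(x, "selected_degrees")
  cat(sprintf("\nselected degrees: (%d, %d)\n", sd[1L], sd[2L]))
  invisible(x)
}

#' @rdname select_ratpoly
#' @param x a `ratpoly_selection` object.
#' @export
selected_model <- function(x) {
  stopifnot(inherits(x, "ratpoly_selection"))
  attr(x, "selected")
}
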