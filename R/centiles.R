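#' Age-specific centile table
#'
#' Turns a fitted mean curve and a sqrt-scale residual SD into normative
#' centiles. Under the package's dispersion rule - homoscedastic Gaussian
#' scatter on the square-root scale - the level at age `a` and probability
#' `p` is \deqn{(\max(0,\; m(a) + z_p\,\sigma))^2,} where `m` is the
#' sqrt-scale mean curve and `z_p` the standard-normal quantile. The 50th
#' centile therefore equals the squared mean curve, and sqrt-scale
#' interval half-widths are the same at every age.
#'
#' @param model a `ratpoly` model.
#' @param sigma_sqrt residual SD on the sqrt scale (e.g. `sqrt(8.1)`).
#' @param ages age grid in years (default integer ages 0-17).
#' @param probabilities centile levels in (0,1); the default matches the
#'   conventional 2.5/10/25/50/75/90/97.5 columns.
#' @return an object of class `ib_centile_table`: a data frame with one
#'   row per age and one column per centile, plus an `age` column.
#' @examples
#' centile_table(ib_reference_model(), sigma_sqrt = sqrt(8.1), ages = 0:2)
#' @export
centile_table <- function(model, sigma_sqrt, ages = 0:17,
                          probabilities = c(0.025, 0.1, 0.25, 0.5,
                                            0.75, 0.9, 0.975)) {
  stopifnot(inherits(model, "ratpoly"))
  if (sigma_sqrt < 0) stop("sigma_sqrt must be >= 0")
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  mu <- predict(model, ages = ages, type = "sqrt")
  z <- stats::qnorm(probabilities)
  vals <- outer(mu, z, function(m, q) pmax(0, m + q * sigma_sqrt)^2)
  out <- data.frame(age = ages, vals)
  names(out) <- c("age", paste0("p", formatC(100 * probabilities,
                                             format = "g")))
  attr(out, "sigma_sqrt") <- sigma_sqrt
  attr(out, "probabilities") <- probabilities
  class(out) <- c("ib_centile_table", "data.frame")
  out
}

#' @export
print.ib_centile_table <- function(x, digits = 0, ...) {
  cat(sprintf("Normative centiles (pg/mL), sigma_sqrt = %.3f\n",
              attr(x, "sigma_sqrt")))
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a centile table as CSV
#'
#' @param x an `ib_centile_table`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_centile_csv <- function(x, path) {
  stopifnot(inherits(x, "ib_centile_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Confidence and prediction bands in pg/mL
#'
#' Convenience wrapper around [predict.ratpoly()] returning, at each age,
#' the fitted mean level, 95% confidence limits for the predicted mean
#' (delta-method propagation of the coefficient covariance through the
#' rational function) and 95% prediction limits for new observations
#' (residual variance added before the normal quantile). The prediction
#' band always encloses the confidence band, which encloses the fit.
#'
#' @param model a fitted `ratpoly` with covariance.
#' @param ages evaluation ages.
#' @param sigma_sqrt residual SD for the prediction limits; defaults to
#'   the model's assessed `sqrt(msr)`.
#' @param level band coverage (default 0.95).
#' @return data frame with columns `age`, `fit`, `ci_low`, `ci_high`,
#'   `pi_low`, `pi_high` (pg/mL).
#' @export
prediction_bands <- function(model, ages = seq(0, 17, by = 0.1),
                             sigma_sqrt = NULL, level = 0.95) {
  ci <- predict(model, ages = ages, type = "level",
                interval = "confidence", level = level)
  pi <- predict(model, ages = ages, type = "level",
                interval = "prediction", level = level,
                sigma_sqrt = sigma_sqrt)
  data.frame(age = ages, fit = ci$fit,
             ci_low = ci$lwr, ci_high = ci$upr,
             pi_low = pi$lwr, pi_high = pi$upr)
}

#' Landmarks of the mean curve
#'
#' Locates the local maxima and minima of the mean level curve on an age
#' interval by dense grid scan plus local refinement, and reports each
#' landmark's age, level and interquartile range under the centile rule.
#' Interval endpoints are reported as boundary landmarks when the curve is
#' monotone into them (e.g. the late-adolescent peak at the upper end of
#' the modelled range).
#'
#' @param model a `ratpoly` model.
#' @param sigma_sqrt residual SD on the sqrt scale for the IQR columns.
#' @param interval age interval to scan (default `c(0, 17)`).
#' @param step grid step in years.
#' @return data frame with columns `type` (`"max"`/`"min"`), `boundary`,
#'   `age`, `level`, `iqr_low`, `iqr_high`.
#' @examples
#' curve_landmarks(ib_reference_model(), sigma_sqrt = sqrt(8.1))
#' @export
curve_landmarks <- function(model, sigma_sqrt = 0, interval = c(0, 17),
                            step = 0.001) {
  stopifnot(inherits(model, "ratpoly"))
  g <- seq(interval[1L], interval[2L], by = step)
  lev <- function(a) predict(model, ages = a, type = "level")
  v <- lev(g)
  rows <- list()
  add <- function(type, boundary, age, level) {
    q <- stats::qnorm(c(0.25, 0.75))
    mu <- predict(model, ages = age, type = "sqrt")
    iqr <- pmax(0, mu + q * sigma_sqrt)^2
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, boundary = boundary, age = age, level = level,
      iqr_low = iqr[1L], iqr_high = iqr[2L], stringsAsFactors = FALSE)
  }
  dv <- diff(v)
  sgn <- sign(dv)
  for (i in which(sgn[-length(sgn)] > 0 & sgn[-1L] <= 0)) {
    o <- stats::optimize(lev, c(g[i], g[i + 2L]), maximum = TRUE,
                         tol = 1e-9)
    add("max", FALSE, o$maximum, o$objective)
  }
  for (i in which(sgn[-length(sgn)] < 0 & sgn[-1L] >= 0)) {
    o <- stats::optimize(lev, c(g[i], g[i + 2L]), tol = 1e-9)
    add("min", FALSE, o$minimum, o$objective)
  }
  # boundary landmarks: the curve is monotone into the endpoints
  if (dv[1L] < 0) add("max", TRUE, g[1L], v[1L]) else
    if (dv[1L] > 0) add("min", TRUE, g[1L], v[1L])
  if (dv[length(dv)] > 0) add("max", TRUE, g[length(g)], v[length(g)]) else
    if (dv[length(dv)] < 0) add("min", TRUE, g[length(g)], v[length(g)])
  out <- do.call(rbind, rows)
  out <- out[order(out$age), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fan chart of the normative centiles
#'
#' @param x an `ib_centile_table`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ib_centile_table <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::matplot(df$age, df[-1L], type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(df) - 1L, "Zissou 1"),
                    xlab = "age (years)", ylab = "inhibin B (pg/mL)", ...)
  graphics::legend("topright", legend = names(df)[-1L], lty = 1, cex = 0.7,
                   col = grDevices::hcl.colors(ncol(df) - 1L, "Zissou 1"))
  invisible(x)
}
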