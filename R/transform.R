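#' Box-Cox power selection by profile likelihood
#'
#' Profiles the Box-Cox log-likelihood of a sample of positive levels over
#' a grid of powers, refines the grid once around the optimum, and returns
#' the maximising power with a 95% profile-likelihood interval (chi-square,
#' 1 df cutoff). A power near 0.5 justifies working on the square-root
#' scale, which is what the rest of the package assumes.
#'
#' Zero levels (the conception anchors) are not admissible here - the
#' log-likelihood is undefined at 0 - so callers pass observational levels
#' only.
#'
#' @param levels positive levels in pg/mL; at least 10 values.
#' @param lower,upper,step profiling grid for the power.
#' @param conf confidence level of the profile interval.
#' @return an object of class `ib_boxcox`: list with `lambda_hat`,
#'   `ci_low`, `ci_high`, and `profile` (data frame of lambda, loglik).
#' @examples
#' set.seed(1)
#' boxcox_lambda(rnorm(200, 10)^2)   # sqrt-normal data: lambda near 0.5
#' @export
boxcox_lambda <- function(levels, lower = -1, upper = 2, step = 0.01,
                          conf = 0.95) {
  levels <- as.numeric(levels)
  if (length(levels) < 10L) stop("need at least 10 values")
  if (any(!is.finite(levels)) || any(levels <= 0))
    stop("all levels must be positive and finite")

  grid <- seq(lower, upper, by = step)
  ll <- vapply(grid, boxcox_loglik, numeric(1L), y = levels)
  i <- which.max(ll)
  # one refinement pass around the coarse optimum
  fine <- seq(max(lower, grid[i] - step), min(upper, grid[i] + step),
              by = step / 10)
  llf <- vapply(fine, boxcox_loglik, numeric(1L), y = levels)
  lam <- c(grid, fine)
  val <- c(ll, llf)
  o <- order(lam)
  lam <- lam[o]; val <- val[o]
  keep <- !duplicated(lam)
  lam <- lam[keep]; val <- val[keep]

  j <- which.max(val)
  cut <- val[j] - stats::qchisq(conf, df = 1) / 2
  inside <- which(val >= cut)
  ci_low <- interp_cross(lam, val, min(inside), cut, left = TRUE)
  ci_high <- interp_cross(lam, val, max(inside), cut, left = FALSE)

  out <- list(lambda_hat = lam[j], ci_low = ci_low, ci_high = ci_high,
              conf = conf, n = length(levels),
              profile = data.frame(lambda = lam, loglik = val))
  class(out) <- "ib_boxcox"
  out
}

# profile log-likelihood of the Box-Cox family for an i.i.d. sample
# (location/scale maximised out analytically)
boxcox_loglik <- function(lambda, y) {
  n <- length(y)
  z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

# linear interpolation of the profile at the cutoff crossing
interp_cross <- function(lam, val, idx, cut, left) {
  k <- if (left) idx - 1L else idx + 1L
  if (k < 1L || k > length(lam)) return(lam[idx])  # cutoff beyond grid edge
  lam[idx] + (lam[k] - lam[idx]) * (cut - val[idx]) / (val[k] - val[idx])
}

#' @export
print.ib_boxcox <- function(x, ...) {
  cat(sprintf("Box-Cox power: lambda = %.3f (%g%% profile CI %.3f-%.3f), n = %d\n",
              x$lambda_hat, 100 * x$conf, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Square-root scale transforms
#'
#' The forward transform takes levels in pg/mL to the square-root scale on
#' which the mean curve is modelled; the inverse squares back and can never
#' return a negative level. `inverse_transform(sqrt_transform(x))` is the
#' identity for valid input.
#'
#' @param levels non-negative levels in pg/mL.
#' @param values sqrt-scale values.
#' @return transformed numeric vector.
#' @export
sqrt_transform <- function(levels) {
  if (any(levels < 0, na.rm = TRUE)) stop("negative level")
  sqrt(levels)
}

#' @rdname sqrt_transform
#' @export
inverse_transform <- function(values) values^2
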