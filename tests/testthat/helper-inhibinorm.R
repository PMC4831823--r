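# shared fixtures, built once per test run

.fixtures <- new.env()

# the default study-conditions cohort: 709 synthetic records, 20 anchors,
# 300 imputed adults; seeds follow the pipeline's derivation from a
# master seed of 1
default_cohort <- function() {
  if (is.null(.fixtures$aug)) {
    d <- generate_cohort(seed = 1)
    .fixtures$base <- d
    .fixtures$anchored <- add_conception_anchors(d)
    .fixtures$aug <- impute_adult_values(.fixtures$anchored, seed = 1001)
  }
  .fixtures$aug
}

default_base <- function() { default_cohort(); .fixtures$base }
default_anchored <- function() { default_cohort(); .fixtures$anchored }

default_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- suppressWarnings(ratpoly(default_cohort()))
  .fixtures$fit
}

# printed reference coefficients, kept here independently of the package
# so evaluation tests do not trust ib_reference_model() for its own check
ref_coefs <- c(a = 15.4403, b = 0.8408, c = 19.6695, d = 0.4985,
               e = -1.0425, f = -0.0402, g = 0.2895, h = 0.0015)

ref_eval_sqrt <- function(x) {
  (ref_coefs["a"] + ref_coefs["c"] * x + ref_coefs["e"] * x^2 +
     ref_coefs["g"] * x^3) /
    (1 + ref_coefs["b"] * x + ref_coefs["d"] * x^2 +
       ref_coefs["f"] * x^3 + ref_coefs["h"] * x^4)
}

tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
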