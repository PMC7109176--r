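#' SUV normalization parameters
#'
#' Body-weight SUV convention: tracer concentration divided by injected
#' dose per unit body weight. The emulated protocol injects 4 MBq of
#' 18F-FDG per kg of body weight, so a uniform tissue concentration equal
#' to dose/weight maps to SUV 1.
#'
#' @param injected_dose Injected activity in MBq; > 0.
#' @param body_weight Body weight in kg; > 0.
#' @param units_in Unit of the activity-concentration map: `"kBq/mL"`
#'   (default) or `"Bq/mL"`.
#' @return An object of class `suv_params`.
#' @export
suv_params <- function(injected_dose, body_weight, units_in = c("kBq/mL", "Bq/mL")) {
  units_in <- match.arg(units_in)
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be > 0 (MBq)")
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0 (kg)")
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 units_in = units_in), class = "suv_params")
}

#' Compute an SUV map from an activity-concentration map
#'
#' `SUV(v) = concentration(v) [kBq/mL] * body_weight [kg] / injected_dose [MBq]`,
#' dimensionless under the g/mL convention. Any tracer decay correction to
#' injection time is an upstream (scanner-side) responsibility and is not
#' applied here.
#'
#' @param activity A [scalar_slice()] of activity concentration (>= 0).
#' @param params A [suv_params()].
#' @return A [scalar_slice()] of SUV.
#' @export
compute_suv <- function(activity, params) {
  stopifnot(inherits(activity, "scalar_slice"), inherits(params, "suv_params"))
  conc <- activity$values
  if (any(conc[is.finite(conc)] < 0)) stop("activity must be non-negative")
  if (params$units_in == "Bq/mL") conc <- conc / 1000
  scalar_slice(conc * params$body_weight / params$injected_dose,
               spacing = activity$spacing, origin = activity$origin)
}

#' Fit a perfusion-insensitive ADC map
#'
#' Per-voxel mono-exponential model `S_b = S_0 * exp(-b * ADC)` fitted by
#' ordinary least squares of `log(S_b)` against `b`, restricted to
#' b >= `b_min` (default 200 s/mm^2) so that the fast pseudo-diffusion
#' (perfusion) signal component present at low b does not inflate the
#' estimate. Voxels with any non-positive signal among the used b-values
#' are flagged invalid (the log transform is undefined there) rather than
#' imputed.
#'
#' @param stack A [dwi_stack()].
#' @param b_min Minimum b-value (s/mm^2) included in the fit; default 200.
#' @param clamp_negative If `TRUE`, negative fitted ADC values are clamped
#'   to zero; default `FALSE` (retained, so downstream consumers can see
#'   them).
#' @return An object of class `adc_fit` with elements `adc` (mm^2/s matrix),
#'   `s0` (extrapolated b=0-reference signal matrix), `valid` (logical
#'   matrix), `bvalues_used`, and the grid geometry (`spacing`, `origin`).
#' @export
fit_adc <- function(stack, b_min = 200, clamp_negative = FALSE) {
  stopifnot(inherits(stack, "dwi_stack"))
  use <- which(stack$bvalues >= b_min)
  if (length(use) < 2L)
    stop("need at least 2 b-values >= b_min (", b_min, ") for the fit")
  b <- stack$bvalues[use]
  d <- dim(stack$signals[[1]])
  n <- prod(d)
  S <- vapply(stack$signals[use], as.numeric, numeric(n))  # n x length(b)
  valid <- rowSums(!is.finite(S) | S <= 0) == 0L
  logS <- matrix(NA_real_, n, length(b))
  logS[valid, ] <- log(S[valid, , drop = FALSE])
  # closed-form simple linear regression of log S on b, vectorized over voxels
  bc <- b - mean(b)
  denom <- sum(bc^2)
  slope <- as.numeric(logS %*% bc) / denom
  intercept <- rowMeans(logS) - slope * mean(b)
  adc <- -slope
  if (clamp_negative) adc <- pmax(adc, 0)
  adc[!valid] <- NA_real_
  s0 <- exp(intercept)
  s0[!valid] <- NA_real_
  structure(list(adc = matrix(adc, d[1], d[2]),
                 s0 = matrix(s0, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2]),
                 bvalues_used = b,
                 spacing = stack$spacing, origin = stack$origin),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat(sprintf("<adc_fit> %d x %d voxels, %d valid, b-values used: %s\n",
              nrow(x$adc), ncol(x$adc), sum(x$valid),
              paste(x$bvalues_used, collapse = ", ")))
  invisible(x)
}

#' Extract the ADC map as a scalar slice
#'
#' @param fit An `adc_fit` object.
#' @param scale Multiplier applied for display; use `1e3` to report in the
#'   conventional x 10^-3 mm^2/s units. Default 1 (mm^2/s).
#' @return A [scalar_slice()]; invalid voxels are `NA`.
#' @export
adc_slice <- function(fit, scale = 1) {
  stopifnot(inherits(fit, "adc_fit"))
  scalar_slice(fit$adc * scale, spacing = fit$spacing, origin = fit$origin)
}
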