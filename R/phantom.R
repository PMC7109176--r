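# Separable Gaussian smoothing with edge replication; sigma in voxels.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  m <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-m, m), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(rep(v[1], m), v, rep(v[length(v)], m))
    as.numeric(stats::filter(padded, k, sides = 2))[(m + 1):(m + length(v))]
  }
  x <- apply(x, 2, conv1)
  t(apply(x, 1, conv1))
}

# Smooth periodic perturbation of the lesion boundary: a few random
# harmonics, standardized to unit sd over the circle. Coefficients are
# drawn once so the same profile can be evaluated at different angles.
draw_harmonics <- function(n_harmonics = 4L) {
  h <- 2:(1 + n_harmonics)
  list(h = h, a = rnorm(n_harmonics, sd = 1 / h),
       b = rnorm(n_harmonics, sd = 1 / h),
       norm = sqrt(sum(1 / h^2)))
}

eval_harmonics <- function(coef, theta) {
  g <- numeric(length(theta))
  for (i in seq_along(coef$h)) {
    g <- g + coef$a[i] * cos(coef$h[i] * theta) +
             coef$b[i] * sin(coef$h[i] * theta)
  }
  g / coef$norm
}

#' Specification of a digital lesion phantom
#'
#' Defines a single-slice breast-lesion phantom: a perturbed-ellipse tumor
#' with spatially correlated heterogeneous FDG uptake above a noisy
#' background, a linear partial-volume rim, co-registered multi-b DWI with
#' reduced diffusivity inside the tumor and Rician noise, a jittered
#' reference mask standing in for a manual DCE delineation, and a
#' treatment-effect fraction `f` that moves uptake and diffusivity toward
#' background, emulating response to neoadjuvant therapy.
#'
#' @param shape Grid (rows, cols); default 96 x 96.
#' @param spacing Voxel size mm; default 2 x 2 (in-plane DWI resolution).
#' @param center_mm Tumor center (mm); default grid center.
#' @param semi_axes_mm Ellipse semi-axes (mm); default c(16, 12), giving a
#'   lesion area near 6 cm^2.
#' @param lobularity Relative amplitude of the smooth boundary
#'   perturbation; 0 = exact ellipse. Default 0.15.
#' @param suv_background,suv_background_sd Background SUV mean and iid
#'   Gaussian sd; defaults 1.0 and 0.1.
#' @param suv_tumor,suv_tumor_sd Tumor SUV mean and heterogeneity sd
#'   (spatially correlated field); defaults 8.0 and 2.0.
#' @param corr_length_mm Correlation length of the intratumoral
#'   heterogeneity field (mm); default 8.
#' @param rim_width_mm Width of the linear partial-volume blend at the
#'   lesion boundary (mm); default 4, the scale of the PET reconstruction
#'   point-spread function.
#' @param adc_tumor,adc_background Diffusivities (mm^2/s); defaults
#'   0.96e-3 (cellular tumor) and 2.0e-3 (normal tissue).
#' @param s0 DWI signal at b = 0; default 1000.
#' @param rician_sigma Rician noise sigma for DWI; default 20 (SNR 50 at
#'   b = 0).
#' @param bvalues b-values (s/mm^2); default c(0, 50, 120, 200, 400, 700).
#' @param treatment_effect Fraction `f` in `[0, 1]`: tumor uptake contrast
#'   is scaled by `1 - f` and tumor ADC moves to
#'   `adc_tumor + f * (adc_background - adc_tumor)`. 0 = untreated.
#' @param dce_jitter_mm Boundary jitter sd (mm) of the reference mask;
#'   default 0.
#' @param dce_offset_mm Rigid offset (mm) of the reference mask; default 0.
#' @param crop_margin_mm Margin around the tumor bounding box for the crop
#'   box; default 8.
#' @param psf_fwhm_mm Gaussian blur FWHM (mm) applied to the final SUV
#'   map, standing in for the PET reconstruction point-spread function;
#'   default 4, the reconstruction filter width of the emulated protocol.
#'   Set 0 to disable.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L), spacing = c(2, 2),
                         center_mm = NULL, semi_axes_mm = c(16, 12),
                         lobularity = 0.15,
                         suv_background = 1.0, suv_background_sd = 0.1,
                         suv_tumor = 8.0, suv_tumor_sd = 2.0,
                         corr_length_mm = 8, rim_width_mm = 4,
                         adc_tumor = 0.96e-3, adc_background = 2.0e-3,
                         s0 = 1000, rician_sigma = 20,
                         bvalues = c(0, 50, 120, 200, 400, 700),
                         treatment_effect = 0,
                         dce_jitter_mm = 0, dce_offset_mm = 0,
                         crop_margin_mm = 8, psf_fwhm_mm = 4, seed = 1L) {
  if (is.null(center_mm))
    center_mm <- (shape - 1) / 2 * spacing
  if (treatment_effect < 0 || treatment_effect > 1)
    stop("treatment_effect must be in [0, 1]")
  if (treatment_effect < 1 && suv_tumor <= suv_background)
    stop("tumor SUV mean must exceed background for an untreated lesion")
  if (adc_tumor >= adc_background)
    stop("tumor ADC must be below background ADC (cellularity convention)")
  if (any(c(suv_background_sd, suv_tumor_sd, rician_sigma,
            dce_jitter_mm) < 0))
    stop("noise/jitter magnitudes must be >= 0")
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               center_mm = as.numeric(center_mm),
               semi_axes_mm = as.numeric(semi_axes_mm),
               lobularity = lobularity,
               suv_background = suv_background,
               suv_background_sd = suv_background_sd,
               suv_tumor = suv_tumor, suv_tumor_sd = suv_tumor_sd,
               corr_length_mm = corr_length_mm, rim_width_mm = rim_width_mm,
               adc_tumor = adc_tumor, adc_background = adc_background,
               s0 = s0, rician_sigma = rician_sigma, bvalues = bvalues,
               treatment_effect = treatment_effect,
               dce_jitter_mm = dce_jitter_mm, dce_offset_mm = dce_offset_mm,
               crop_margin_mm = crop_margin_mm, psf_fwhm_mm = psf_fwhm_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Normalized elliptical radius and angle of every voxel relative to a center.
ellipse_coords <- function(shape, spacing, center_mm, semi_axes_mm) {
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  dx <- outer(xs - center_mm[1], rep(1, shape[2]))
  dy <- outer(rep(1, shape[1]), ys - center_mm[2])
  u <- dx / semi_axes_mm[1]
  v <- dy / semi_axes_mm[2]
  list(rr = sqrt(u^2 + v^2), theta = atan2(v, u),
       # mm length of one unit of normalized radius along each direction
       lmm = 1 / sqrt((cos(atan2(v, u)) / semi_axes_mm[1])^2 +
                      (sin(atan2(v, u)) / semi_axes_mm[2])^2))
}

#' Generate a digital lesion phantom
#'
#' Deterministic given the spec (including its seed). Returns co-registered
#' SUV map, DWI stack, ground-truth tumor mask, reference (DCE-proxy)
#' mask, and a crop box containing the lesion with margin.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_case` with elements `suv`
#'   ([scalar_slice()]), `dwi` ([dwi_stack()]), `truth`, `reference`
#'   ([binary_mask()]s), `crop` ([crop_box()]), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    sh <- spec$shape; sp <- spec$spacing
    f <- spec$treatment_effect

    ec <- ellipse_coords(sh, sp, spec$center_mm, spec$semi_axes_mm)
    shape_coef <- draw_harmonics()
    jitter_coef <- draw_harmonics()
    boundary <- 1 + spec$lobularity *
      matrix(eval_harmonics(shape_coef, as.numeric(ec$theta)), sh[1], sh[2])
    boundary <- pmax(boundary, 0.3)
    truth <- ec$rr <= boundary
    if (!any(truth)) stop("tumor lies outside the grid or has zero extent")
    if (any(truth[c(1, sh[1]), ]) || any(truth[, c(1, sh[2])]))
      stop("tumor extends to the grid edge; enlarge the grid")

    # partial-volume rim: linear blend 1 -> 0 across rim_width_mm outside
    # the true boundary; zero width gives a hard edge
    if (spec$rim_width_mm > 0) {
      delta <- spec$rim_width_mm / ec$lmm  # rim width in normalized radius
      alpha <- pmin(pmax((boundary + delta - ec$rr) / delta, 0), 1)
    } else {
      alpha <- matrix(0, sh[1], sh[2])
    }
    alpha[truth] <- 1

    # heterogeneous uptake: correlated Gaussian field inside the lesion
    het <- matrix(rnorm(prod(sh)), sh[1], sh[2])
    sig_vox <- spec$corr_length_mm / mean(sp)
    het <- gaussian_smooth(het, sig_vox)
    hsd <- sd(as.numeric(het))
    if (hsd > 0) het <- het / hsd
    tumor_field <- spec$suv_tumor + spec$suv_tumor_sd * het

    bg_field <- spec$suv_background +
      rnorm(prod(sh), sd = spec$suv_background_sd)
    suv_vals <- matrix(bg_field, sh[1], sh[2]) +
      alpha * (1 - f) * (tumor_field - spec$suv_background)
    if (spec$psf_fwhm_mm > 0)
      suv_vals <- gaussian_smooth(suv_vals,
                                  spec$psf_fwhm_mm / 2.3548 / mean(sp))
    suv_vals <- pmax(suv_vals, 0)

    # diffusivity: sharp transition at the true boundary
    adc_tumor_eff <- spec$adc_tumor +
      f * (spec$adc_background - spec$adc_tumor)
    adc_map <- matrix(spec$adc_background, sh[1], sh[2])
    adc_map[truth] <- adc_tumor_eff

    signals <- lapply(spec$bvalues, function(b) {
      s <- spec$s0 * exp(-b * adc_map)
      if (spec$rician_sigma > 0) {
        e1 <- matrix(rnorm(prod(sh), sd = spec$rician_sigma), sh[1], sh[2])
        e2 <- matrix(rnorm(prod(sh), sd = spec$rician_sigma), sh[1], sh[2])
        s <- sqrt((s + e1)^2 + e2^2)
      }
      s
    })

    # reference mask: the same lesion boundary, jittered and rigidly offset
    phi <- runif(1, 0, 2 * pi)
    if (spec$dce_offset_mm == 0 && spec$dce_jitter_mm == 0) {
      reference <- truth
    } else {
      ref_center <- spec$center_mm +
        spec$dce_offset_mm * c(cos(phi), sin(phi))
      ec_ref <- ellipse_coords(sh, sp, ref_center, spec$semi_axes_mm)
      theta_ref <- as.numeric(ec_ref$theta)
      ref_boundary <- 1 + spec$lobularity *
        matrix(eval_harmonics(shape_coef, theta_ref), sh[1], sh[2])
      ref_boundary <- pmax(ref_boundary, 0.3)
      jit <- spec$dce_jitter_mm *
        matrix(eval_harmonics(jitter_coef, theta_ref), sh[1], sh[2]) /
        ec_ref$lmm
      reference <- ec_ref$rr <= pmax(ref_boundary + jit, 0.2)
    }

    # crop: tumor bounding box plus margin, clipped to the grid
    idx <- which(truth, arr.ind = TRUE)
    mrow <- ceiling(spec$crop_margin_mm / sp[1])
    mcol <- ceiling(spec$crop_margin_mm / sp[2])
    box <- crop_box(max(min(idx[, 1]) - 1L - mrow, 0L),
                    min(max(idx[, 1]) + mrow, sh[1]),
                    max(min(idx[, 2]) - 1L - mcol, 0L),
                    min(max(idx[, 2]) + mcol, sh[2]))

    structure(list(
      suv = scalar_slice(suv_vals, spacing = sp),
      dwi = dwi_stack(signals, spec$bvalues, spacing = sp),
      truth = binary_mask(truth, spacing = sp),
      reference = binary_mask(reference, spacing = sp),
      crop = box, spec = spec), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %d x %d grid, truth %d voxels, f = %.2f, seed %d\n",
              x$spec$shape[1], x$spec$shape[2], sum(x$truth$mask),
              x$spec$treatment_effect, x$spec$seed))
  invisible(x)
}

#' Simulate a cohort of lesion phantoms
#'
#' Draws per-case parameter variation around a base spec and generates
#' untreated (`f = 0`) and treated cases; treated cases draw the
#' treatment-effect fraction from `f_range`. Per-case sub-seeds are derived
#' reproducibly from `seed`, and every drawn parameter is recorded in the
#' manifest.
#'
#' @param n_untreated,n_treated Numbers of cases per group (>= 1).
#' @param base_spec A [phantom_spec()] providing the central parameter
#'   values; its jitter/offset fields are used as-is.
#' @param size_jitter Relative sd of the lognormal semi-axis variation;
#'   default 0.35, chosen so the cohort's lesion-area spread matches the
#'   roughly twenty-fold tumor-volume range seen in locally advanced
#'   breast cancer cohorts.
#' @param uptake_jitter Relative sd of the lognormal tumor-SUV variation;
#'   default 0.15.
#' @param adc_jitter Relative sd of the lognormal tumor-ADC variation;
#'   default 0.1.
#' @param f_range Range of the treated-group treatment-effect draw;
#'   default c(0.3, 0.9).
#' @param seed Master seed for the cohort.
#' @return A list of class `phantom_cohort`: `cases` (list of
#'   `phantom_case`), `manifest` (data frame, one row per case with every
#'   drawn parameter).
#' @export
simulate_cohort <- function(n_untreated = 24L, n_treated = 29L,
                            base_spec = phantom_spec(),
                            size_jitter = 0.35, uptake_jitter = 0.15,
                            adc_jitter = 0.1, f_range = c(0.3, 0.9),
                            seed = 1L) {
  if (n_untreated < 1L || n_treated < 1L) stop("need >= 1 case per group")
  n <- n_untreated + n_treated
  groups <- rep(c("untreated", "treated"), c(n_untreated, n_treated))
  draws <- withr::with_seed(seed, {
    data.frame(
      case_id = sprintf("case%03d", seq_len(n)),
      group = groups,
      sub_seed = sample.int(.Machine$integer.max - 1L, n),
      axis_a = base_spec$semi_axes_mm[1] * exp(rnorm(n, sd = size_jitter)),
      axis_b = base_spec$semi_axes_mm[2] * exp(rnorm(n, sd = size_jitter)),
      suv_tumor = base_spec$suv_tumor * exp(rnorm(n, sd = uptake_jitter)),
      adc_tumor = base_spec$adc_tumor * exp(rnorm(n, sd = adc_jitter)),
      f = ifelse(groups == "treated",
                 runif(n, f_range[1], f_range[2]), 0),
      stringsAsFactors = FALSE)
  })
  cases <- lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$semi_axes_mm <- c(draws$axis_a[i], draws$axis_b[i])
    sp$suv_tumor <- draws$suv_tumor[i]
    sp$adc_tumor <- min(draws$adc_tumor[i], 0.95 * base_spec$adc_background)
    sp$treatment_effect <- draws$f[i]
    sp$seed <- draws$sub_seed[i]
    make_phantom(sp)
  })
  names(cases) <- draws$case_id
  structure(list(cases = cases, manifest = draws), class = "phantom_cohort")
}
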