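#' k-means++ seeding for 1-D cluster centers
#'
#' The first center is drawn uniformly from the data; each subsequent
#' center is drawn with probability proportional to the squared distance
#' to the nearest already-chosen center. Deterministic given `seed`.
#'
#' @param values Numeric vector.
#' @param k Number of centers; the data must contain at least `k` distinct
#'   values.
#' @param seed Integer seed.
#' @return Numeric vector of `k` initial centers.
#' @export
kmeanspp_init <- function(values, k, seed = 1L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(unique(values)) < k)
    stop("need at least ", k, " distinct values for k-means++ with k = ", k)
  withr::with_seed(seed, {
    n <- length(values)
    centers <- numeric(k)
    centers[1] <- values[sample.int(n, 1L)]
    if (k > 1L) {
      d2 <- (values - centers[1])^2
      for (c_i in 2:k) {
        # all mass may sit on a few points; sample() handles zero weights
        centers[c_i] <- values[sample.int(n, 1L, prob = d2)]
        d2 <- pmin(d2, (values - centers[c_i])^2)
      }
    }
    centers
  })
}

gauss_loglik <- function(x, w, mu, sigma2) {
  dens <- vapply(seq_along(w),
                 function(c_i) w[c_i] * dnorm(x, mu[c_i], sqrt(sigma2[c_i])),
                 numeric(length(x)))
  sum(log(pmax(rowSums(dens), .Machine$double.xmin)))
}

em_once <- function(x, k, centers, tol, max_iter, var_floor) {
  n <- length(x)
  mu <- centers
  sigma2 <- rep(max(var(x), var_floor), k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: responsibilities in log space for stability
    logd <- vapply(seq_len(k),
                   function(c_i) log(w[c_i]) +
                     dnorm(x, mu[c_i], sqrt(sigma2[c_i]), log = TRUE),
                   numeric(n))
    m <- apply(logd, 1L, max)
    r <- exp(logd - m)
    rs <- rowSums(r)
    ll <- sum(m + log(rs))
    r <- r / rs
    ll_trace <- c(ll_trace, ll)
    # M-step
    nk <- colSums(r)
    nk <- pmax(nk, .Machine$double.xmin)
    w <- nk / n
    mu <- as.numeric(crossprod(r, x)) / nk
    sigma2 <- vapply(seq_len(k),
                     function(c_i) sum(r[, c_i] * (x - mu[c_i])^2) / nk[c_i],
                     numeric(1))
    sigma2 <- pmax(sigma2, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma2 = sigma2, ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = iter, converged = converged)
}

#' Fit a univariate Gaussian mixture by EM with k-means++ restarts
#'
#' Standard expectation-maximization for a `k`-component univariate
#' Gaussian mixture: the E-step computes posterior responsibilities
#' `r_ic` proportional to `w_c * N(x_i; mu_c, sigma_c^2)`, the M-step
#' re-estimates weights, means and variances from the weighted data.
#' Each restart is seeded by k-means++; the restart with the highest
#' final log-likelihood wins. Components are relabeled in ascending order
#' of mean, matching the background / unknown / tumor semantics of the
#' three-class segmentation (lowest, intermediate, highest intensity).
#'
#' @param values Numeric vector; needs at least `2 * k` distinct values.
#' @param k Number of components (default 3).
#' @param seed Integer seed; restart sub-seeds are derived from it.
#' @param n_restarts Number of k-means++ restarts (default 5).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param max_iter Iteration cap per restart (default 500). Hitting the cap
#'   returns `converged = FALSE`, not an error.
#' @param var_floor_frac Variance floor as a fraction of the data variance
#'   (default 1e-6), preventing component collapse.
#' @return An object of class `mixture_fit`: `weights`, `means`,
#'   `variances` (sorted by ascending mean), `log_likelihood`, `ll_trace`,
#'   `n_iter`, `converged`, `degenerate` (any floored-variance component
#'   with weight < 1e-6), `k`, `n`.
#' @export
fit_gmm <- function(values, k = 3L, seed = 1L, n_restarts = 5L,
                    tol = 1e-6, max_iter = 500L, var_floor_frac = 1e-6) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L * k)
    stop("need at least ", 2L * k,
         " distinct values to identify a ", k, "-component mixture")
  var_floor <- max(var_floor_frac * var(x), .Machine$double.xmin)
  sub_seeds <- seed + seq_len(n_restarts) - 1L
  best <- NULL
  for (r_i in seq_len(n_restarts)) {
    centers <- kmeanspp_init(x, k, seed = sub_seeds[r_i])
    fit <- em_once(x, k, centers, tol, max_iter, var_floor)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  ord <- order(best$mu, best$sigma2)
  degenerate <- any(best$sigma2 <= var_floor * (1 + 1e-12) & best$w < 1e-6)
  structure(list(weights = best$w[ord], means = best$mu[ord],
                 variances = best$sigma2[ord],
                 log_likelihood = best$ll, ll_trace = best$ll_trace,
                 n_iter = best$n_iter, converged = best$converged,
                 degenerate = degenerate, k = k, n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d components on %d values, logLik %.3f (%s after %d iter)\n",
              x$k, x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  lab <- if (x$k == 3L) c("background", "unknown", "tumor")
         else paste0("c", seq_len(x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  %-10s w = %.3f, mean = %.3f, sd = %.3f\n",
                lab[i], x$weights[i], x$means[i], sqrt(x$variances[i])))
  invisible(x)
}

#' Hard class assignment under a fitted mixture
#'
#' Assigns each value to the component with the highest weighted density
#' `w_c * N(x; mu_c, sigma_c^2)` (maximum posterior probability). Ties go
#' to the lower-mean class.
#'
#' @param fit A [fit_gmm()] result.
#' @param values Numeric vector.
#' @return Integer vector of component indices (1 = lowest mean =
#'   background, `k` = highest mean = tumor); named with the three-class
#'   labels when `k = 3`.
#' @export
class_assign <- function(fit, values) {
  stopifnot(inherits(fit, "mixture_fit"))
  x <- as.numeric(values)
  logd <- vapply(seq_len(fit$k),
                 function(c_i) log(fit$weights[c_i]) +
                   dnorm(x, fit$means[c_i], sqrt(fit$variances[c_i]), log = TRUE),
                 numeric(length(x)))
  if (length(x) == 1L) logd <- matrix(logd, nrow = 1L)
  # which.max returns the FIRST maximum; components are sorted by mean, so
  # ties already break toward the lower-mean class
  cls <- apply(logd, 1L, which.max)
  if (fit$k == 3L)
    names(cls) <- c("background", "unknown", "tumor")[cls]
  cls
}

#' Tumor threshold from the tumor/unknown density intersection
#'
#' Solves `w_u * N(x; mu_u, s_u^2) = w_t * N(x; mu_t, s_t^2)` for the
#' unknown (intermediate) and tumor (highest-mean) components by equating
#' the log weighted densities, a quadratic in `x` (linear when the
#' variances are equal). The smallest root strictly inside
#' `(mu_unknown, mu_tumor)` is the decision boundary; if no root falls in
#' that open interval the midpoint `(mu_u + mu_t)/2` is used and flagged.
#' The background component plays no role in the crossing.
#'
#' @param fit A 3-component [fit_gmm()] result with
#'   `mu_unknown < mu_tumor` strictly.
#' @return A list: `threshold` (SUV), `fallback` (`TRUE` if the midpoint
#'   fallback was used).
#' @export
tumor_threshold <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$k < 3L) stop("tumor_threshold requires a 3-component fit")
  mu_u <- fit$means[2]; s2_u <- fit$variances[2]; w_u <- fit$weights[2]
  mu_t <- fit$means[3]; s2_t <- fit$variances[3]; w_t <- fit$weights[3]
  if (!(mu_u < mu_t)) stop("degenerate fit: unknown mean not below tumor mean")
  # log(w_u) - log(s_u) - (x-mu_u)^2/(2 s2_u) = log(w_t) - log(s_t) - (x-mu_t)^2/(2 s2_t)
  A <- 1 / (2 * s2_t) - 1 / (2 * s2_u)
  B <- mu_u / s2_u - mu_t / s2_t
  C <- mu_t^2 / (2 * s2_t) - mu_u^2 / (2 * s2_u) +
    log(w_u) - log(w_t) + 0.5 * (log(s2_t) - log(s2_u))
  roots <- if (abs(A) < .Machine$double.eps * max(1, abs(B))) {
    if (B == 0) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > mu_u & roots < mu_t]
  if (length(inside) == 0L) {
    list(threshold = (mu_u + mu_t) / 2, fallback = TRUE)
  } else {
    list(threshold = min(inside), fallback = FALSE)
  }
}

seg_result <- function(mask, method, threshold, fit = NULL, flags = character(0)) {
  structure(list(mask = mask, method = method, threshold = threshold,
                 fit = fit, flags = flags),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method %s, threshold %s, %d voxels in mask%s\n",
              x$method,
              if (is.null(x$threshold) || is.na(x$threshold)) "-"
              else sprintf("%.4g", x$threshold),
              sum(x$mask$mask),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' GMM tumor segmentation of a cropped SUV slice
#'
#' Fits the three-class mixture to all voxel values of the crop, derives
#' the tumor/unknown intersection threshold, and returns the mask of
#' voxels with SUV strictly above it. Voxels of the intermediate "unknown"
#' class are thereby treated as non-tumor, a compromise that avoids
#' overestimation from partial-volume voxels at the lesion rim. No
#' connected-component filtering is applied.
#'
#' @param cropped_suv A [scalar_slice()] restricted to the lesion crop.
#' @inheritParams fit_gmm
#' @return A `segmentation_result` with `method = "gmm_pet"`, the mask (on
#'   the crop grid), the applied `threshold`, the `mixture_fit`, and any
#'   diagnostic flags (`"midpoint_fallback"`, `"not_converged"`,
#'   `"degenerate"`).
#' @export
segment_gmm <- function(cropped_suv, seed = 1L, n_restarts = 5L,
                        tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(cropped_suv, "scalar_slice"))
  fit <- fit_gmm(cropped_suv$values, k = 3L, seed = seed,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter)
  th <- tumor_threshold(fit)
  flags <- character(0)
  if (th$fallback) flags <- c(flags, "midpoint_fallback")
  if (!fit$converged) flags <- c(flags, "not_converged")
  if (fit$degenerate) flags <- c(flags, "degenerate")
  m <- cropped_suv$values > th$threshold
  m[!is.finite(cropped_suv$values)] <- FALSE
  seg_result(binary_mask(m, spacing = cropped_suv$spacing,
                         origin = cropped_suv$origin),
             "gmm_pet", th$threshold, fit = fit, flags = flags)
}

#' Fixed-SUV threshold segmentation
#'
#' `mask = {SUV > t}` with strict inequality; the conventional fixed
#' cut-off is SUV 2.5. The mask may be empty: treated lesions whose
#' uptake has fallen below the cut-off yield no tumor area, which is
#' flagged rather than treated as an error.
#'
#' @param cropped_suv A [scalar_slice()].
#' @param t SUV threshold (default 2.5).
#' @return A `segmentation_result` with `method = "suv_fixed"`.
#' @export
segment_fixed <- function(cropped_suv, t = 2.5) {
  stopifnot(inherits(cropped_suv, "scalar_slice"))
  m <- cropped_suv$values > t
  m[!is.finite(cropped_suv$values)] <- FALSE
  flags <- if (!any(m)) "empty_mask" else character(0)
  seg_result(binary_mask(m, spacing = cropped_suv$spacing,
                         origin = cropped_suv$origin),
             "suv_fixed", t, flags = flags)
}

#' Percent-of-maximum threshold segmentation
#'
#' `threshold = frac * max(SUV)` within the crop (default 42% of maximum);
#' the mask is `{SUV >= threshold}` (inclusive, so the maximum voxel is
#' always retained and the mask is never empty). Invariant to positive
#' rescaling of the SUV map.
#'
#' @param cropped_suv A [scalar_slice()].
#' @param frac Fraction of the maximum (default 0.42).
#' @return A `segmentation_result` with `method = "suv_percent_max"`.
#' @export
segment_percent_max <- function(cropped_suv, frac = 0.42) {
  stopifnot(inherits(cropped_suv, "scalar_slice"))
  v <- cropped_suv$values
  if (!any(is.finite(v))) stop("crop contains no finite SUV values")
  th <- frac * max(v[is.finite(v)])
  m <- v >= th
  m[!is.finite(v)] <- FALSE
  seg_result(binary_mask(m, spacing = cropped_suv$spacing,
                         origin = cropped_suv$origin),
             "suv_percent_max", th)
}

#' Serialize a mixture fit (and threshold) to JSON
#'
#' @param seg A `segmentation_result` from [segment_gmm()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_result"))
  obj <- list(method = seg$method, threshold = seg$threshold,
              flags = seg$flags)
  if (!is.null(seg$fit)) {
    obj$weights <- seg$fit$weights
    obj$means <- seg$fit$means
    obj$variances <- seg$fit$variances
    obj$log_likelihood <- seg$fit$log_likelihood
    obj$n_iter <- seg$fit$n_iter
    obj$converged <- seg$fit$converged
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
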