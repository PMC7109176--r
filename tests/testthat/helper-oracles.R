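# Shared fixture builders and independent oracles for the test suite.

sample_mixture <- function(n, w, mu, sdv) {
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  rnorm(n, mu[comp], sdv[comp])
}

# grid-scan oracle for the weighted-density crossing between the two
# upper mixture components, independent of the closed-form solver
grid_threshold <- function(fit, step = 1e-5) {
  mu_u <- fit$means[2]; mu_t <- fit$means[3]
  xs <- seq(mu_u + step, mu_t - step, by = step)
  g <- log(fit$weights[2]) + dnorm(xs, mu_u, sqrt(fit$variances[2]), log = TRUE) -
       log(fit$weights[3]) - dnorm(xs, mu_t, sqrt(fit$variances[3]), log = TRUE)
  sg <- which(diff(sign(g)) != 0)
  if (length(sg) == 0) return(NA_real_)
  i <- sg[1]
  # linear interpolation inside the bracketing step
  xs[i] + step * g[i] / (g[i] - g[i + 1])
}

random_valid_fit <- function() {
  mu <- sort(runif(3, 0, 10))
  while (mu[3] - mu[2] < 0.5) mu <- sort(runif(3, 0, 10))
  w <- runif(3, 0.05, 1); w <- w / sum(w)
  structure(list(weights = w, means = mu,
                 variances = runif(3, 0.05, 1.5)^2,
                 k = 3L, n = 100L), class = "mixture_fit")
}

# definitional BH step-up brute force: with p sorted ascending,
# adjusted_i = min over the tail j >= i of p_j * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(pmin(ranked[i:m] * m / (i:m), 1))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

make_decay_stack <- function(adc_map, s0 = 1000,
                             bvalues = c(0, 50, 120, 200, 400, 700),
                             sigma = 0, spacing = c(2, 2)) {
  signals <- lapply(bvalues, function(b) {
    s <- s0 * exp(-b * adc_map)
    if (sigma > 0) {
      e1 <- matrix(rnorm(length(s), sd = sigma), nrow(s))
      e2 <- matrix(rnorm(length(s), sd = sigma), nrow(s))
      s <- sqrt((s + e1)^2 + e2^2)
    }
    s
  })
  dwi_stack(signals, bvalues, spacing = spacing)
}

mask_from_idx <- function(idx, shape = c(12, 12), spacing = c(2, 2),
                          origin = c(0, 0)) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[idx] <- TRUE
  binary_mask(m, spacing = spacing, origin = origin)
}

fake_adc <- function(values, valid = NULL, spacing = c(2, 2), origin = c(0, 0)) {
  if (is.null(valid)) valid <- is.finite(values)
  structure(list(adc = values, s0 = values * 0 + 1, valid = valid,
                 bvalues_used = c(200, 400, 700),
                 spacing = spacing, origin = origin), class = "adc_fit")
}
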