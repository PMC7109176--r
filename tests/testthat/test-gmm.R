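test_that("k-means++ picks one center per well-separated plateau", {
  vals <- c(0, 0, 0, 10, 10, 10, 20, 20, 20)
  for (s in 1:100) {
    ctr <- kmeanspp_init(vals, 3, seed = s)
    expect_equal(sort(ctr), c(0, 10, 20))
  }
  expect_true(kmeanspp_init(vals, 1, seed = 1) %in% vals)
  expect_error(kmeanspp_init(c(1, 1, 2, 2, 3, 3), 4, seed = 1), "distinct")
  expect_identical(kmeanspp_init(vals, 3, seed = 5),
                   kmeanspp_init(vals, 3, seed = 5))
})

test_that("EM recovers a well-separated 3-component mixture", {
  withr::with_seed(11, {
    x <- sample_mixture(3000, c(0.5, 0.3, 0.2), c(1, 3, 8), c(0.3, 0.5, 1.0))
  })
  fit <- fit_gmm(x, seed = 2)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$means - c(1, 3, 8))), 0.1)
  expect_lt(max(abs(fit$weights - c(0.5, 0.3, 0.2))), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means) >= 0))
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit$ll_trace) > -1e-8 * abs(fit$ll_trace[-1])))
})

test_that("tight separated clusters are recovered almost exactly", {
  withr::with_seed(3, {
    x <- c(rnorm(100, 0, 0.01), rnorm(100, 5, 0.01), rnorm(100, 10, 0.01))
  })
  fit <- fit_gmm(x, seed = 1)
  expect_lt(max(abs(fit$means - c(0, 5, 10))), 0.01)
  expect_lt(max(abs(fit$weights - 1 / 3)), 0.01)
})

test_that("parameter recovery holds across repeated seeded simulations", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      x <- sample_mixture(2500, c(0.4, 0.35, 0.25), c(0, 4, 9),
                          c(0.5, 0.6, 0.8))
      fit <- fit_gmm(x, seed = rep)
      expect_lt(max(abs(fit$means - c(0, 4, 9))), 0.15)
      expect_true(all(diff(fit$ll_trace) > -1e-8 * abs(fit$ll_trace[-1])))
    }
  })
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_gmm(rep(2.5, 50)), "distinct")
  expect_error(fit_gmm(c(1, 2, 3, 4, 5)), "distinct")
  # near-degenerate: one effective component still returns a fit object
  withr::with_seed(5, x <- rnorm(200, 1, 0.05))
  fit <- fit_gmm(x, seed = 1)
  expect_s3_class(fit, "mixture_fit")
})

test_that("class assignment equals the independent weighted-density argmax", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      fit <- random_valid_fit()
      x <- runif(50, -2, 12)
      cls <- class_assign(fit, x)
      dens <- vapply(1:3, function(c_i)
        fit$weights[c_i] * dnorm(x, fit$means[c_i], sqrt(fit$variances[c_i])),
        numeric(50))
      expect_equal(unname(cls), apply(dens, 1, which.max))
    }
  })
  # at a well-separated tumor mean the class is tumor
  fit <- structure(list(weights = rep(1 / 3, 3), means = c(1, 5, 9),
                        variances = rep(0.25, 3), k = 3L, n = 10L),
                   class = "mixture_fit")
  expect_equal(unname(class_assign(fit, 9)), 3L)
  expect_equal(names(class_assign(fit, 9)), "tumor")
  # midpoint tie between two equal-weight equal-variance classes goes low
  expect_equal(unname(class_assign(fit, 7)), 2L)
})

test_that("the symmetric intersection threshold is the midpoint", {
  fit <- structure(list(weights = c(0.4, 0.3, 0.3), means = c(0, 3, 8),
                        variances = c(1, 1, 1), k = 3L, n = 10L),
                   class = "mixture_fit")
  th <- tumor_threshold(fit)
  expect_false(th$fallback)
  expect_equal(th$threshold, 5.5, tolerance = 1e-12)
})

test_that("threshold matches the dense grid-scan crossing oracle", {
  fit <- structure(list(weights = c(0.5, 0.3, 0.2), means = c(0, 3, 8),
                        variances = c(0.3, 0.5^2, 1.0^2), k = 3L, n = 10L),
                   class = "mixture_fit")
  th <- tumor_threshold(fit)
  expect_equal(th$threshold, grid_threshold(fit), tolerance = 1e-4)

  withr::with_seed(31, {
    n_checked <- 0
    for (rep in 1:40) {
      f <- random_valid_fit()
      th <- tumor_threshold(f)
      g <- grid_threshold(f)
      if (th$fallback) {
        expect_true(is.na(g))  # solver and scan agree there is no crossing
      } else {
        n_checked <- n_checked + 1
        expect_lt(abs(th$threshold - g), 1e-4)
      }
    }
    expect_gt(n_checked, 20)
  })
})

test_that("threshold shifts toward the tumor mean as tumor weight vanishes", {
  mk <- function(wt) structure(
    list(weights = c(0.5, 1 - 0.5 - wt, wt), means = c(0, 3, 8),
         variances = c(1, 1, 1), k = 3L, n = 10L), class = "mixture_fit")
  ths <- vapply(c(0.3, 0.1, 0.03, 0.01), function(w) tumor_threshold(mk(w))$threshold,
                numeric(1))
  expect_true(all(diff(ths) > 0))
  expect_error(tumor_threshold(structure(
    list(weights = rep(1 / 3, 3), means = c(1, 5, 5), variances = rep(1, 3),
         k = 3L, n = 10L), class = "mixture_fit")), "degenerate")
})

test_that("GMM segmentation recovers a three-level phantom crop", {
  withr::with_seed(13, {
    tumor <- matrix(rnorm(15 * 15, 8, 0.3), 15, 15)
    rim <- matrix(rnorm(30 * 30, 4, 0.3), 30, 30)
    bg <- matrix(rnorm(30 * 30, 1, 0.1), 30, 30)
  })
  vals <- bg
  vals[5:26, 5:26] <- rim[5:26, 5:26]
  vals[8:22, 8:22] <- tumor
  sl <- scalar_slice(vals, spacing = c(2, 2))
  truth <- binary_mask({m <- matrix(FALSE, 30, 30); m[8:22, 8:22] <- TRUE; m},
                       spacing = c(2, 2))
  seg <- segment_gmm(sl, seed = 4)
  expect_gte(dice(seg$mask, truth), 0.9)
  # mask is exactly the strict exceedance of the returned threshold
  expect_identical(seg$mask$mask, sl$values > seg$threshold)
  # threshold lies between the unknown and tumor means (or is the midpoint)
  expect_gt(seg$threshold, seg$fit$means[2])
  expect_lt(seg$threshold, seg$fit$means[3])
})

test_that("fixed threshold uses strict exceedance and may come back empty", {
  low <- scalar_slice(matrix(c(1, 2, 2.4, 0.5), 2, 2))
  seg <- segment_fixed(low)
  expect_equal(sum(seg$mask$mask), 0)
  expect_true("empty_mask" %in% seg$flags)

  uniform <- scalar_slice(matrix(3, 4, 4))
  expect_true(all(segment_fixed(uniform)$mask$mask))

  boundary <- scalar_slice(matrix(c(2.5, 2.5 + 1e-9), 1, 2))
  segb <- segment_fixed(boundary)
  expect_identical(as.vector(segb$mask$mask), c(FALSE, TRUE))
})

test_that("percent-max threshold is inclusive and scale invariant", {
  vals <- matrix(c(10, 4.2, 4.1999, 1), 2, 2)
  seg <- segment_percent_max(scalar_slice(vals))
  expect_equal(seg$threshold, 4.2)
  expect_identical(seg$mask$mask, vals >= 4.2)
  expect_true(seg$mask$mask[1, 1])  # the max voxel always survives

  uniform <- scalar_slice(matrix(5, 3, 3))
  expect_true(all(segment_percent_max(uniform)$mask$mask))

  withr::with_seed(17, r <- matrix(runif(64, 0, 10), 8, 8))
  m1 <- segment_percent_max(scalar_slice(r))$mask$mask
  m2 <- segment_percent_max(scalar_slice(r * 7.3))$mask$mask
  expect_identical(m1, m2)
  # the fixed threshold, by contrast, is not scale invariant
  f1 <- segment_fixed(scalar_slice(r))$mask$mask
  f2 <- segment_fixed(scalar_slice(r * 7.3))$mask$mask
  expect_false(identical(f1, f2))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(23, {
    x <- sample_mixture(2000, c(0.5, 0.3, 0.2), c(1, 3.5, 8), c(0.4, 0.5, 0.9))
  })
  fit <- fit_gmm(x, seed = 1)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-3)
})

test_that("mixture fits serialize to JSON with threshold and diagnostics", {
  withr::with_seed(2, {
    x <- sample_mixture(1200, c(0.5, 0.25, 0.25), c(1, 4, 9), c(0.3, 0.5, 0.8))
  })
  seg <- segment_gmm(scalar_slice(matrix(x, 30, 40)), seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(seg, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$method, "gmm_pet")
  expect_equal(length(obj$means), 3)
  expect_equal(obj$threshold, seg$threshold, tolerance = 1e-9)
})
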