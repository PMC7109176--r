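test_that("phantoms are deterministic given the spec", {
  sp <- phantom_spec(seed = 5, dce_jitter_mm = 1, dce_offset_mm = 1,
                     treatment_effect = 0.4)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$suv$values, b$suv$values)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_identical(a$reference$mask, b$reference$mask)
  expect_identical(lapply(a$dwi$signals, identity),
                   lapply(b$dwi$signals, identity))
  c_ <- make_phantom(phantom_spec(seed = 6, dce_jitter_mm = 1,
                                  dce_offset_mm = 1, treatment_effect = 0.4))
  expect_false(identical(a$suv$values, c_$suv$values))
})

test_that("with no jitter or offset the reference mask equals the truth", {
  ph <- make_phantom(phantom_spec(seed = 2, dce_jitter_mm = 0,
                                  dce_offset_mm = 0))
  expect_identical(ph$reference$mask, ph$truth$mask)
})

test_that("an unperturbed ellipse discretizes to the expected area", {
  # semi-axes 10 x 14 mm on a 2 mm grid; analytic area pi*10*14 = 4.40 cm^2
  ph <- make_phantom(phantom_spec(semi_axes_mm = c(10, 14), lobularity = 0,
                                  seed = 3))
  n <- sum(ph$truth$mask)
  # brute-force discretized-ellipse count as the oracle
  cx <- ph$spec$center_mm[1]; cy <- ph$spec$center_mm[2]
  cnt <- 0
  for (i in 0:95) for (j in 0:95) {
    if (((i * 2 - cx) / 10)^2 + ((j * 2 - cy) / 14)^2 <= 1) cnt <- cnt + 1
  }
  expect_equal(n, cnt)
  # within one voxel-ring of the analytic area: ring area ~ perimeter x spacing
  perimeter_mm <- pi * (3 * (10 + 14) - sqrt((3 * 10 + 14) * (10 + 3 * 14))) / 2
  ring_cm2 <- perimeter_mm * 2 / 100
  expect_lt(abs(n * 0.04 - pi * 10 * 14 / 100), ring_cm2)
})

test_that("zero-noise phantoms recover the prescribed diffusivities exactly", {
  ph <- make_phantom(phantom_spec(seed = 4, rician_sigma = 0))
  fit <- fit_adc(ph$dwi)
  expect_true(all(fit$valid))
  expect_equal(max(abs(fit$adc[ph$truth$mask] - 0.96e-3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(fit$adc[!ph$truth$mask] - 2.0e-3)), 0, tolerance = 1e-12)

  # treated condition moves tumor ADC toward background
  f <- 0.5
  pht <- make_phantom(phantom_spec(seed = 4, rician_sigma = 0,
                                   treatment_effect = f))
  expected <- 0.96e-3 + f * (2.0e-3 - 0.96e-3)
  fitt <- fit_adc(pht$dwi)
  expect_equal(max(abs(fitt$adc[pht$truth$mask] - expected)), 0,
               tolerance = 1e-12)
})

test_that("reference-truth Dice rises monotonically as jitter shrinks", {
  jit <- c(4, 2, 1, 0.5, 0)
  dices <- vapply(jit, function(j) {
    ph <- make_phantom(phantom_spec(seed = 9, dce_jitter_mm = j))
    dice(ph$reference, ph$truth)
  }, numeric(1))
  expect_true(all(diff(dices) >= 0))
  expect_equal(dices[length(jit)], 1)
})

test_that("a noiseless homogeneous lesion is exactly recovered by percent-max", {
  ph <- make_phantom(phantom_spec(seed = 12, suv_background_sd = 0,
                                  suv_tumor_sd = 0, rim_width_mm = 0,
                                  lobularity = 0, psf_fwhm_mm = 0))
  cropped <- crop_slice(ph$suv, ph$crop)
  seg <- segment_percent_max(cropped, frac = 0.42)
  full <- uncrop_mask(seg$mask, ph$crop, dim(ph$suv$values))
  expect_equal(dice(full, ph$truth), 1)
})

test_that("strong treatment effect pushes uptake below the fixed threshold", {
  ph <- make_phantom(phantom_spec(seed = 6, treatment_effect = 0.9))
  cropped <- crop_slice(ph$suv, ph$crop)
  expect_lt(max(cropped$values), 2.5)
  seg <- segment_fixed(cropped)
  expect_equal(sum(seg$mask$mask), 0)
  expect_true("empty_mask" %in% seg$flags)
})

test_that("phantom spec validation catches contradictory physiology", {
  expect_error(phantom_spec(suv_tumor = 0.5, suv_background = 1), "exceed")
  expect_error(phantom_spec(adc_tumor = 2e-3, adc_background = 1e-3),
               "below background")
  expect_error(phantom_spec(treatment_effect = 1.2), "\\[0, 1\\]")
  expect_error(make_phantom(phantom_spec(semi_axes_mm = c(200, 200))), "grid")
})

test_that("cohort simulation is reproducible and respects the design", {
  co <- simulate_cohort(4, 5, seed = 42)
  expect_length(co$cases, 9)
  expect_equal(nrow(co$manifest), 9)
  expect_equal(sum(co$manifest$group == "untreated"), 4)
  expect_equal(sum(co$manifest$group == "treated"), 5)
  expect_true(all(co$manifest$f[co$manifest$group == "untreated"] == 0))
  expect_true(all(co$manifest$f[co$manifest$group == "treated"] >= 0.3 &
                    co$manifest$f[co$manifest$group == "treated"] <= 0.9))

  co2 <- simulate_cohort(4, 5, seed = 42)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$cases[[7]]$suv$values, co2$cases[[7]]$suv$values)

  # treated lesions have lower peak uptake by construction
  peak <- vapply(co$cases, function(cs) max(cs$suv$values), numeric(1))
  expect_lt(mean(peak[co$manifest$group == "treated"]),
            mean(peak[co$manifest$group == "untreated"]))
})
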