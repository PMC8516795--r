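test_that("trials are bit-reproducible from the seed", {
  a <- generate_trial(16, distortion_spec(seed = 77))
  b <- generate_trial(16, distortion_spec(seed = 77))
  expect_identical(a$encoding$fixations, b$encoding$fixations)
  expect_identical(a$recall$fixations, b$recall$fixations)
  expect_identical(a$truth, b$truth)
  c <- generate_trial(16, distortion_spec(seed = 78))
  expect_false(identical(a$encoding$fixations, c$encoding$fixations))
  # the generator does not disturb the ambient RNG stream
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(generate_trial(16, distortion_spec(seed = 9)))
  expect_identical(runif(1), x1)
})

test_that("zero distortion and pure translation are generated exactly", {
  z <- distortion_spec(rotation_deg = 0, translation_px = c(0, 0),
                       scale_bias = 1, deform_amp_px = 0,
                       jitter_sigma_px = 0, retention = 1,
                       n_spurious = 0, seed = 2)
  tr <- generate_trial(16, z)
  expect_equal(length(tr$recall), 16)
  expect_equal(positions(tr$recall),
               positions(tr$encoding)[tr$truth, ], ignore_attr = TRUE)
  tp <- distortion_spec(rotation_deg = 0, translation_px = c(50, 0),
                        scale_bias = 1, deform_amp_px = 0,
                        jitter_sigma_px = 0, retention = 0.5,
                        n_spurious = 0, seed = 2)
  tr2 <- generate_trial(16, tp)
  expect_equal(positions(tr2$recall),
               sweep(positions(tr2$encoding)[tr2$truth, ], 2, c(50, 0), `+`),
               ignore_attr = TRUE)
})

test_that("the default spec yields 10 retained + 1 spurious recall fixations", {
  tr <- generate_trial(16, distortion_spec(seed = 1))
  expect_equal(length(tr$recall), 11)
  expect_equal(sum(!is.na(tr$truth)), 10)    # round(0.65 * 16)
  expect_equal(sum(is.na(tr$truth)), 1)
  # spurious fixations fall in the central 80% of the image
  sp <- positions(tr$recall)[is.na(tr$truth), , drop = FALSE]
  expect_true(all(sp[, 1] >= 0.1 * 1024 & sp[, 1] <= 0.9 * 1024))
  expect_true(all(sp[, 2] >= 0.1 * 768 & sp[, 2] <= 0.9 * 768))
  # truth covers every recall fixation
  expect_equal(length(tr$truth), length(tr$recall))
  expect_true(all(is.na(tr$truth) == is.na(tr$true_positions[, 1])))
})

test_that("distortion magnitudes are honoured within Monte-Carlo error", {
  # deformation-only world: displacement RMS should equal deform_amp_px
  d <- distortion_spec(rotation_deg = 0, translation_px = c(0, 0),
                       scale_bias = 1, deform_amp_px = 20,
                       jitter_sigma_px = 0, retention = 1, n_spurious = 0)
  disp2 <- unlist(lapply(1:60, function(s) {
    d$seed <- 1000 + s
    tr <- generate_trial(16, d)
    rowSums((positions(tr$recall) - tr$true_positions)^2)
  }))
  expect_equal(sqrt(mean(disp2)), 20, tolerance = 0.15)
  # jitter-only world: mean displacement = Rayleigh mean sigma * sqrt(pi/2)
  j <- distortion_spec(rotation_deg = 0, translation_px = c(0, 0),
                       scale_bias = 1, deform_amp_px = 0,
                       jitter_sigma_px = 5, retention = 1, n_spurious = 0)
  dm <- unlist(lapply(1:60, function(s) {
    j$seed <- 2000 + s
    tr <- generate_trial(16, j)
    sqrt(rowSums((positions(tr$recall) - tr$true_positions)^2))
  }))
  expect_equal(mean(dm), 5 * sqrt(pi / 2), tolerance = 0.1)
})

test_that("encoding entropy sits in the calibrated mid range", {
  ent <- vapply(default_suite(30, base_seed = 42), function(tr) {
    fixation_entropy_2d(positions(tr$encoding), c(1024, 768))
  }, numeric(1))
  expect_gt(mean(ent), 0.3)
  expect_lt(mean(ent), 0.47)   # clearly below the 16-point ceiling of 0.5
})

test_that("recovery_experiment recovers the undistorted world", {
  z <- distortion_spec(rotation_deg = 0, translation_px = c(0, 0),
                       scale_bias = 1, deform_amp_px = 0,
                       jitter_sigma_px = 0, retention = 1, n_spurious = 0)
  rec <- recovery_experiment(n_trials = 10, spec = z, base_seed = 2)
  # every encoding fixation matched at epsilon = 1 deg
  expect_equal(unname(rec$summary["mean_matched_fraction_relocated"]), 1)
  expect_equal(unname(rec$summary["mean_false_match_fraction"]), 0)
  # consensus averaging across within-cluster neighbours leaves a small
  # residual even with no distortion (see the methods vignette); it stays
  # well under the matching radius
  expect_lt(unname(rec$summary["mean_relocation_error_deg"]), 0.15)
  expect_equal(unname(rec$summary["convergence_rate"]), 1)
})

test_that("spec validation rejects impossible worlds", {
  expect_error(distortion_spec(retention = 0), "retention")
  expect_error(distortion_spec(retention = 1.2), "retention")
  expect_error(distortion_spec(deform_scale_px = 0), "deform_scale")
  expect_error(distortion_spec(n_spurious = -1), "n_spurious")
  expect_error(generate_trial(1, distortion_spec()), "n_encoding")
})
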