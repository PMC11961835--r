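test_that("phantom generation is a pure function of its spec", {
  spec <- phantom_spec(subclones = list(list(offset_mm = c(2, 2, 0),
                                             radius_mm = 4, suv = 15)),
                       noise_sd = 0.3, seed = 77)
  a <- make_phantom(spec); b <- make_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)

  spec2 <- spec; spec2$seed <- 78L
  c2 <- make_phantom(spec2)
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
  expect_identical(a$mask$voxels, c2$mask$voxels)  # noise never moves the mask
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(shape = c(10, 10, 10), spacing = c(2, 2, 2),
                            lesion_radius_mm = 12),
               "exceeds the grid")
  expect_error(make_phantom(phantom_spec(
    lesion_radius_mm = 8,
    subclones = list(list(offset_mm = c(7, 0, 0), radius_mm = 3, suv = 12)))),
    "outside the lesion")
})

test_that("a noiseless phantom without subclones is perfectly homogeneous", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, seed = 1))
  f <- extract_features(ph$volume, ph$mask)
  expect_identical(f$auc_csh, 1)

  hot <- make_phantom(phantom_spec(
    subclones = list(list(offset_mm = c(2, 0, 0), radius_mm = 4,
                          suv = 18)),
    noise_sd = 0, seed = 1))
  f_hot <- extract_features(hot$volume, hot$mask)
  expect_lt(f_hot$auc_csh, f$auc_csh)
})

test_that("simulated response reproduces the prescribed volume shrinkage", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, seed = 3))
  wk3 <- apply_response(ph, response_spec(volume_shrink_frac = 0.5,
                                          suv_decline_frac = 0))
  f0 <- extract_features(ph$volume, ph$mask)
  f3 <- extract_features(wk3$volume, wk3$mask)
  d <- delta_features(f0, f3)
  expect_lt(abs(d$d_mtv + 50), 1)      # within one voxel of -50%
  expect_lt(abs(d$d_suv_max), 1e-9)    # no uptake decline requested
  expect_true(all(wk3$mask$voxels[ph$mask$voxels == FALSE] == FALSE))
})

test_that("a fully persistent hot subclone increases heterogeneity", {
  ph <- make_phantom(phantom_spec(
    subclones = list(list(offset_mm = c(2, -1, 0), radius_mm = 4.5,
                          suv = 15)),
    base_suv = 5, noise_sd = 0.2, seed = 8))
  wk3 <- apply_response(ph, response_spec(volume_shrink_frac = 0.2,
                                          suv_decline_frac = 0.4,
                                          subclone_persistence = 1.0))
  f0 <- extract_features(ph$volume, ph$mask)
  f3 <- extract_features(wk3$volume, wk3$mask)
  d <- delta_features(f0, f3)
  expect_lt(d$d_auc_csh, 0)
})

test_that("uniform decline leaves AUC-CSH unchanged up to bin granularity", {
  ph <- make_phantom(phantom_spec(base_suv = 6, noise_sd = 0.4, seed = 12))
  wk3 <- apply_response(ph, response_spec(volume_shrink_frac = 0,
                                          suv_decline_frac = 0.3))
  f0 <- extract_features(ph$volume, ph$mask)
  f3 <- extract_features(wk3$volume, wk3$mask)
  # AUC-CSH is quantised at one bin relative to SUVmax, so a uniform
  # rescaling can shift it by about bin_width/SUVmax at each timepoint
  granularity <- 0.3 / f0$suv_max + 0.3 / f3$suv_max
  expect_lt(abs(f3$auc_csh - f0$auc_csh), granularity)
})

test_that("a shrink that removes every voxel is rejected", {
  tiny <- make_phantom(phantom_spec(lesion_radius_mm = 2.5, noise_sd = 0,
                                    seed = 1))
  expect_error(apply_response(tiny, response_spec(volume_shrink_frac = 0.99)),
               "no lesion voxel")
})

test_that("zero hazards produce an event-free cohort with flat KM", {
  sim <- simulate_cohort(cohort_spec(n_patients = 200,
                                     group_hazards = c(0, 0, 0), seed = 6))
  expect_equal(sum(sim$cohort$lrr_event), 0)
  k <- km_fit(sim$cohort$followup_months, sim$cohort$lrr_event)
  expect_true(all(k$table$survival == 1))
})

test_that("cohort simulation is deterministic and exponentially calibrated", {
  spec <- cohort_spec(n_patients = 5000, group_fractions = c(1, 0, 0),
                      group_hazards = c(0.01, 0, 0), seed = 21)
  sim <- simulate_cohort(spec)
  sim2 <- simulate_cohort(spec)
  expect_identical(sim$cohort, sim2$cohort)
  k24 <- survival_at(km_fit(sim$cohort$followup_months,
                            sim$cohort$lrr_event), 24)
  expect_lt(abs(k24 - exp(-0.24)), 0.02)
})

test_that("group-wise KM matches each group's configured survival", {
  spec <- cohort_spec(n_patients = 6000,
                      group_fractions = c(1, 1, 1) / 3,
                      group_s24 = c(0.93, 0.70, 0.17), seed = 22)
  sim <- simulate_cohort(spec)
  for (g in 1:3) {
    sub <- sim$cohort[sim$cohort$true_group == g, ]
    k24 <- survival_at(km_fit(sub$followup_months, sub$lrr_event), 24)
    expect_lt(abs(k24 - c(0.93, 0.70, 0.17)[g]), 0.03)
  }
})

test_that("the pipeline recovers simulated favourable volume responders", {
  sim <- simulate_cohort(cohort_spec(n_patients = 150, seed = 55),
                         images = TRUE)
  g <- stratify_mtv_csh(sim$deltas$d_mtv, sim$deltas$d_auc_csh)
  fav <- sim$cohort$true_group == 1
  expect_gte(mean(as.integer(g)[fav] == 1L), 0.95)
})
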