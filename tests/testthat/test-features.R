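test_that("fixed-bin discretisation follows the half-open bin convention", {
  cfg <- discretisation_config(bin_width_suv = 0.3, anchor = 0)
  expect_equal(discretise(c(0.0, 0.29, 0.3, 0.95), cfg), c(0L, 0L, 1L, 3L))
  expect_equal(discretise(c(0.1, 5, 900), discretisation_config(1e9)),
               c(0L, 0L, 0L))
  expect_error(discretise(numeric(0), cfg), "no SUV")

  # uniform SUVs in [0, 12) with width 0.3: only indices 0..39 can occur
  suvs <- cshpet:::with_seed(1, runif(1000, 0, 12))
  idx <- discretise(suvs, cfg)
  expect_equal(max(idx), 39L)
  expect_true(all(idx >= 0L))
  expect_lte(length(unique(idx)), 40L)
})

test_that("first-order features match constant-field arithmetic", {
  v <- suv_volume(array(5, c(10, 10, 1)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(10, 10, 1)), reference = v)
  f <- first_order_features(v, m)   # 100 voxels of 0.008 mL at SUV 5
  expect_equal(f$suv_max, 5); expect_equal(f$suv_mean, 5)
  expect_equal(f$mtv_ml, 0.8); expect_equal(f$tlg, 4.0)

  v2 <- suv_volume(array(c(2, 6), c(2, 1, 1)), spacing = c(2, 2, 2))
  m2 <- roi_mask(array(1, c(2, 1, 1)), reference = v2)
  f2 <- first_order_features(v2, m2)
  expect_equal(f2$suv_max, 6); expect_equal(f2$suv_mean, 4)
  expect_equal(f2$mtv_ml, 0.016); expect_equal(f2$tlg, 0.064)

  expect_error(first_order_features(v, roi_mask(array(0, c(10, 10, 1)),
                                                reference = v)),
               "no voxels")
})

test_that("first-order features equal the all-voxel-loop oracle", {
  for (seed in 1:25) {
    ph <- random_phantom(seed)
    f <- first_order_features(ph$volume, ph$mask)
    o <- oracle_first_order(ph$volume, ph$mask)
    for (nm in names(o))
      expect_lt(abs(f[[nm]] - o[[nm]]) / abs(o[[nm]]), 1e-12)
    expect_identical(f$tlg, f$suv_mean * f$mtv_ml)
  }
})

test_that("CSH curve hits the brute-force threshold sweep", {
  # single occupied bin: the degenerate two-point curve
  v <- suv_volume(array(5, c(3, 3, 3)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(3, 3, 3)), reference = v)
  cv <- csh_curve(v, m)
  expect_equal(cv$x, c(0, 1)); expect_equal(cv$y, c(1, 1))

  # two-level field: half the voxels in the top bin
  a <- array(c(rep(10.0, 4), rep(5.05, 4)), c(2, 2, 2))
  v2 <- suv_volume(a, spacing = c(2, 2, 2))
  m2 <- roi_mask(array(1, c(2, 2, 2)), reference = v2)
  cv2 <- csh_curve(v2, m2)
  expect_equal(cv2$y[1], 1)
  suvs <- as.vector(a)
  for (i in seq_along(cv2$x)[-1]) {
    level <- cv2$x[i] * max(oracle_bin_centres(suvs))
    expect_equal(cv2$y[i], oracle_frac_at(suvs, level))
  }
  expect_equal(cv2$y[length(cv2$y)], 0.5)

  # strictly increasing ramp across 64 distinct bins
  ramp <- (0:63 + 0.5) * 0.3
  v3 <- suv_volume(array(ramp, c(4, 4, 4)), spacing = c(1, 1, 1))
  m3 <- roi_mask(array(1, c(4, 4, 4)), reference = v3)
  cv3 <- csh_curve(v3, m3)
  expect_equal(length(cv3$x), 65)
  expect_equal(diff(cv3$y[-1]), rep(-1 / 64, 63))
})

test_that("AUC-CSH equals 1 for homogeneous uptake and rejects bad curves", {
  v <- suv_volume(array(7.3, c(4, 4, 4)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(4, 4, 4)), reference = v)
  expect_identical(auc_csh(csh_curve(v, m)), 1)

  expect_error(auc_csh(list(x = c(0, 0.5), y = c(1, 1))), "malformed")
  expect_error(auc_csh(list(x = c(0, 0.5, 1), y = c(1, 0.4, 0.8))),
               "malformed")
  expect_error(auc_csh(list(x = c(0, 1.2), y = c(1, 1))), "malformed")
})

test_that("AUC-CSH agrees with dense-grid numeric integration", {
  for (seed in c(3, 17, 23)) {
    ph <- random_phantom(seed)
    got <- auc_csh(csh_curve(ph$volume, ph$mask))
    want <- oracle_csh_auc(ph$volume$voxels[ph$mask$voxels])
    expect_lt(abs(got - want), 1e-4)
  }
})

test_that("a hot minority subvolume strictly lowers AUC-CSH", {
  n <- 1000
  uniform <- suv_volume(array(4, c(10, 10, 10)), spacing = c(2, 2, 2))
  hot_vals <- c(rep(12, n / 10), rep(4, 9 * n / 10))
  hot <- suv_volume(array(hot_vals, c(10, 10, 10)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(10, 10, 10)), reference = uniform)
  expect_lt(auc_csh(csh_curve(hot, m)), auc_csh(csh_curve(uniform, m)))
})

test_that("AUC-CSH is invariant when SUVs and bin width scale together", {
  ph <- random_phantom(11)
  base <- auc_csh(csh_curve(ph$volume, ph$mask))
  for (c_scale in c(0.25, 3, 17)) {
    v <- ph$volume
    v$voxels <- v$voxels * c_scale
    cfg <- discretisation_config(bin_width_suv = 0.3 * c_scale)
    expect_equal(auc_csh(csh_curve(v, ph$mask, cfg)), base, tolerance = 1e-12)
  }
})

test_that("mixing in hotter minority populations never raises AUC-CSH", {
  for (seed in 1:20) {
    vals <- cshpet:::with_seed(seed, {
      base <- runif(1, 2, 6)
      n <- 500
      frac <- runif(1, 0.05, 0.3)
      mult <- runif(1, 2, 4)
      list(plain = rep(base, n),
           mixed = c(rep(base * mult, round(n * frac)),
                     rep(base, n - round(n * frac))))
    })
    mk <- function(x) {
      v <- suv_volume(array(x, c(length(x), 1, 1)), spacing = c(2, 2, 2))
      list(v = v, m = roi_mask(array(1, dim(v$voxels)), reference = v))
    }
    a <- mk(vals$plain); b <- mk(vals$mixed)
    expect_lte(auc_csh(csh_curve(b$v, b$m)), auc_csh(csh_curve(a$v, a$m)))
  }
})

test_that("extract_features bundles the five parameters consistently", {
  # homogeneity limit
  v <- suv_volume(array(5, c(5, 5, 5)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(5, 5, 5)), reference = v)
  f <- extract_features(v, m)
  expect_identical(f$auc_csh, 1)
  expect_equal(f$suv_mean, f$suv_max)

  # single-voxel ROI is homogeneous by definition
  m1 <- array(0, c(5, 5, 5)); m1[3, 3, 3] <- 1
  f1 <- extract_features(v, roi_mask(m1, reference = v))
  expect_identical(f1$auc_csh, 1)
  expect_equal(f1$mtv_ml, 0.008)

  expect_named(as.data.frame(f),
               c("scan_id", "timepoint", "suv_max", "suv_mean", "mtv_ml",
                 "tlg", "auc_csh", "bin_width", "anchor"))
})

test_that("the seeded heterogeneous fixture matches its frozen values", {
  # "hetero-A": one hot subclone on a noisy lesion; golden values frozen
  # from the brute-force oracles at first build
  ph <- make_phantom(phantom_spec(
    shape = c(24, 24, 24), spacing = c(2, 2, 2), background_suv = 0.4,
    lesion_radius_mm = 11, base_suv = 5,
    subclones = list(list(offset_mm = c(3, -2, 1), radius_mm = 4.5,
                          suv = 13)),
    noise_sd = 0.25, seed = 2024))
  f <- extract_features(ph$volume, ph$mask)
  golden <- c(suv_max = 13.5276526486527, suv_mean = 5.52326996654578,
              mtv_ml = 5.376, tlg = 29.6930993401501,
              auc_csh = 0.404402145473574)
  for (nm in names(golden))
    expect_equal(f[[nm]], unname(golden[nm]), tolerance = 1e-9)
})
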