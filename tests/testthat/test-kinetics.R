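test_that("delta-M is the voxelwise mean of control minus tag", {
  vol <- array(100, c(2, 2, 2, 4))
  vol[1, 1, 1, ] <- c(104, 100, 106, 100)  # diffs 4 and 6 -> mean 5
  s <- asl_series(vol)
  dm <- compute_delta_m(s)
  expect_equal(dm[1, 1, 1], 5)
  expect_equal(dm[2, 2, 2], 0)
  expect_equal(attr(dm, "n_pairs"), 2L)

  # control == tag everywhere -> identically zero
  s0 <- asl_series(array(7, c(2, 2, 2, 6)))
  expect_true(all(compute_delta_m(s0) == 0))
})

test_that("malformed series are rejected", {
  expect_error(asl_series(array(0, c(2, 2, 2, 5))), "odd")
  expect_error(asl_series(array(0, c(2, 2, 2, 1))), "pair")
  expect_error(asl_series(array(0, c(2, 2, 2))), "4-D")
})

test_that("M0 is the first frame, unmodified", {
  vol <- array(rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6))
  s <- asl_series(vol)
  expect_identical(extract_m0(s), vol[, , , 1])
  expect_equal(dim(extract_m0(s)), dim(vol)[1:3])
})

test_that("simulator round trip at zero noise recovers delta-M and M0", {
  ph <- simulate_asl_series(small_spec())
  expect_equal(compute_delta_m(ph$series), ph$delta_m_true,
               ignore_attr = TRUE)
  expect_identical(extract_m0(ph$series), ph$m0_true)
})

test_that("slice TI2 is affine in slice index", {
  p <- acquisition_params()
  expect_equal(slice_ti2(p, 0), 1800)
  expect_equal(slice_ti2(p, 17) - slice_ti2(p, 0), 17 * p$slice_dt_ms)
  idx <- 0:17
  expect_equal(diff(slice_ti2(p, idx)), rep(p$slice_dt_ms, 17))
  expect_error(slice_ti2(p, -1), "nonnegative")
})

test_that("q matches the protocol reference constants and a numeric oracle", {
  p <- acquisition_params()
  expect_equal(round(compute_q(p, "gray", 1800), 2), 0.93)
  q_white <- compute_q(p, "white", 1800)
  expect_lt(abs(q_white - 0.85) / 0.85, 0.02)

  # independent numeric integration of the same relaxation physics,
  # including the mixed interval where part of the bolus is still vascular
  for (t in c(1500, 1650, 1800, 2100, 2500)) {
    expect_equal(compute_q(p, "gray", t),
                 q_oracle(t, 700, 1664, 1300, 1000), tolerance = 1e-8)
    expect_equal(compute_q(p, "white", t),
                 q_oracle(t, 700, 1664, 1000, 1000), tolerance = 1e-8)
  }
})

test_that("q lies in (0, 1], gray exceeds white, and q -> 1 as rates match", {
  p <- acquisition_params()
  ts <- seq(1500, 4000, by = 100)
  qg <- compute_q(p, "gray", ts)
  qw <- compute_q(p, "white", ts)
  expect_true(all(qg > 0 & qg <= 1))
  expect_true(all(qw > 0 & qw <= 1))
  expect_true(all(qg > qw))
  p_eq <- acquisition_params(t1_tissue_gray_ms = 1664)
  expect_equal(compute_q(p_eq, "gray", 1800), 1, tolerance = 1e-12)
  expect_error(compute_q(p, "gray", 100), "TI1")
})

test_that("quantification inverts the forward model exactly at zero noise", {
  ph <- simulate_asl_series(small_spec())
  p <- acquisition_params()
  tm <- true_masks(ph)
  f <- quantify_perfusion(compute_delta_m(ph$series), extract_m0(ph$series),
                          p, tm)
  err <- abs(f - ph$cbf_true) / ph$cbf_true
  expect_lt(max(err, na.rm = TRUE), 1e-6)
  expect_true(all(is.na(f[ph$tissue == 0L])))
  expect_equal(attr(f, "units"), "mL/100g/min")
})

test_that("quantification is linear in delta-M and scale invariant", {
  ph <- simulate_asl_series(small_spec())
  p <- acquisition_params()
  tm <- true_masks(ph)
  dm <- compute_delta_m(ph$series)
  m0 <- extract_m0(ph$series)
  f1 <- quantify_perfusion(dm, m0, p, tm)
  f2 <- quantify_perfusion(2 * dm, m0, p, tm)
  expect_equal(f2, 2 * f1)
  # global rescaling of the raw signal leaves perfusion unchanged
  f3 <- quantify_perfusion(3.7 * dm, 3.7 * m0, p, tm)
  expect_equal(f3, f1)
  # zero difference -> zero perfusion inside the brain
  f0 <- quantify_perfusion(array(0, dim(dm)), m0, p, tm)
  expect_true(all(f0[ph$tissue > 0L] == 0))
})

test_that("quantification rejects bad inputs and flags low M0", {
  ph <- simulate_asl_series(small_spec())
  p <- acquisition_params()
  tm <- true_masks(ph)
  dm <- compute_delta_m(ph$series)
  m0 <- extract_m0(ph$series)
  expect_error(quantify_perfusion(dm[, , 1:3], m0, p, tm), "geometry")
  expect_error(quantify_perfusion(dm, array(0, dim(m0)), p, tm),
               "degenerate")
  m0_low <- m0
  m0_low[9, 9, 3] <- 1e-6   # brain voxel below the floor
  f <- quantify_perfusion(dm, m0_low, p, tm)
  expect_true(is.na(f[9, 9, 3]))
  expect_true(attr(f, "invalid")[9, 9, 3])
})

test_that("omitting the slice increment reproduces progressive underestimation", {
  spec <- small_spec(cbf_white = 60)  # uniform true CBF across tissues
  ph <- simulate_asl_series(spec)
  tm <- true_masks(ph)
  dm <- compute_delta_m(ph$series)
  m0 <- extract_m0(ph$series)
  gray_profile <- function(f) {
    f[ph$tissue != 2L] <- NA_real_
    prof <- apply(f, 3, mean, na.rm = TRUE)
    prof[!is.nan(prof)]
  }
  p_flat <- acquisition_params(slice_dt_ms = 0)
  f_flat <- quantify_perfusion(dm, m0, p_flat, tm)
  sl_mean <- gray_profile(f_flat)
  expect_true(all(diff(sl_mean) < 0))
  expect_lt(sl_mean[length(sl_mean)], 60)
  # with the increment applied, recovery is slice independent
  f_ok <- quantify_perfusion(dm, m0, acquisition_params(), tm)
  sl_ok <- gray_profile(f_ok)
  expect_lt(sd(sl_ok) / mean(sl_ok), 1e-6)
})

test_that("acquisition parameter invariants are enforced", {
  expect_error(acquisition_params(alpha = 0), "alpha")
  expect_error(acquisition_params(alpha = 1.2), "alpha")
  expect_error(acquisition_params(ti1_ms = 1900), "smaller")
  expect_error(acquisition_params(t1_arterial_ms = -5), "positive")
  p <- acquisition_params()
  expect_equal(p$ti2_base_ms, 1800)
  expect_equal(p$slice_dt_ms, (2500 - 1800) / 9)
})
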