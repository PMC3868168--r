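make_lut <- function() {
  data.frame(label = 1:8,
             region = paste0(rep(c("lh_", "rh_"), each = 4),
                             rep(c("frontal", "parietal", "temporal",
                                   "occipital"), 2)),
             lobe = rep(c("frontal", "parietal", "temporal", "occipital"), 2),
             hemisphere = rep(c("left", "right"), each = 4),
             stringsAsFactors = FALSE)
}

test_that("region statistics filter to the physiological band inclusively", {
  perf <- array(NA_real_, c(3, 1, 1))
  perf[, 1, 1] <- c(0.5, 50, 150)
  labels <- array(1L, c(3, 1, 1))
  lut <- make_lut()
  rt <- region_stats(perf, labels, lut)
  r1 <- rt[rt$label == 1L, ]
  expect_equal(r1$mean_perf, 50)
  expect_equal(r1$n_voxels, 1)
  # boundary values 1 and 100 are admitted
  perf[, 1, 1] <- c(1, 100, 100.0001)
  rt <- region_stats(perf, labels, lut)
  expect_equal(rt$n_voxels[rt$label == 1L], 2)
  # constant region: SD 0; empty region reported missing, not zero
  perf[, 1, 1] <- c(70, 70, 70)
  rt <- region_stats(perf, labels, lut)
  expect_equal(rt$mean_perf[rt$label == 1L], 70)
  expect_equal(rt$sd_perf[rt$label == 1L], 0)
  expect_true(is.na(rt$mean_perf[rt$label == 2L]))
  expect_equal(rt$n_voxels[rt$label == 2L], 0)
})

test_that("region statistics match a brute-force voxel loop on a phantom", {
  set.seed(11)
  spec <- small_spec()
  lb <- simulate_labels(spec)
  perf <- array(rnorm(prod(spec$dim), 55, 30), spec$dim)
  perf[lb$values == 0L] <- NA_real_
  rt <- region_stats(perf, lb$values, lb$lut, low = 1, high = 100)
  for (l in lb$lut$label) {
    vals <- c()
    for (i in seq_len(spec$dim[1])) for (j in seq_len(spec$dim[2]))
      for (k in seq_len(spec$dim[3]))
        if (lb$values[i, j, k] == l && !is.na(perf[i, j, k]) &&
            perf[i, j, k] >= 1 && perf[i, j, k] <= 100)
          vals <- c(vals, perf[i, j, k])
    row <- rt[rt$label == l, ]
    expect_equal(row$n_voxels, length(vals))
    expect_equal(row$mean_perf, mean(vals))
    expect_equal(row$sd_perf, sd(vals))
  }
})

test_that("widening the filter band never loses voxels", {
  set.seed(12)
  spec <- small_spec()
  lb <- simulate_labels(spec)
  perf <- array(rnorm(prod(spec$dim), 55, 40), spec$dim)
  narrow <- region_stats(perf, lb$values, lb$lut, low = 10, high = 90)
  wide <- region_stats(perf, lb$values, lb$lut, low = 1, high = 100)
  expect_true(all(wide$n_voxels >= narrow$n_voxels))
  expect_error(region_stats(perf, lb$values, lb$lut, low = 5, high = 5),
               "smaller")
})

test_that("lobar composites average hemispheres symmetrically", {
  lut <- make_lut()
  rt <- data.frame(lut, n_voxels = 10L,
                   mean_perf = NA_real_, sd_perf = 1)
  rt$mean_perf[rt$lobe == "frontal" & rt$hemisphere == "left"] <- 40
  rt$mean_perf[rt$lobe == "frontal" & rt$hemisphere == "right"] <- 60
  rt$mean_perf[is.na(rt$mean_perf)] <- 50
  lp <- lobar_perfusion(rt)
  expect_equal(lp$perfusion[lp$lobe == "frontal"], 50)
  # swapping hemisphere assignments changes nothing
  rt_sw <- rt
  rt_sw$hemisphere <- ifelse(rt$hemisphere == "left", "right", "left")
  expect_equal(lobar_perfusion(rt_sw)$perfusion, lp$perfusion)
  # single-hemisphere lobe: that hemisphere's value, flagged
  rt1 <- rt[!(rt$lobe == "occipital" & rt$hemisphere == "right"), ]
  expect_warning(lp1 <- lobar_perfusion(rt1), "single hemisphere")
  expect_equal(lp1$perfusion[lp1$lobe == "occipital"], 50)
  expect_equal(lp1$n_hemispheres[lp1$lobe == "occipital"], 1L)
})

test_that("lobar aggregation equals brute-force voxel-level recomputation", {
  set.seed(13)
  spec <- small_spec()
  lb <- simulate_labels(spec)
  perf <- array(rnorm(prod(spec$dim), 55, 10), spec$dim)
  rt <- region_stats(perf, lb$values, lb$lut, low = -1e9, high = 1e9)
  lp <- lobar_perfusion(rt)
  for (lobe in unique(lb$lut$lobe)) {
    hemi_means <- sapply(c("left", "right"), function(h) {
      labs <- lb$lut$label[lb$lut$lobe == lobe & lb$lut$hemisphere == h]
      mean(perf[lb$values %in% labs])
    })
    expect_equal(lp$perfusion[lp$lobe == lobe], mean(hemi_means))
  }
  # literal sum mode: sum of region means per hemisphere, then averaged
  lps <- lobar_perfusion(rt, agg = "sum")
  fr <- rt[rt$lobe == "frontal", ]
  expect_equal(lps$perfusion[lps$lobe == "frontal"],
               mean(tapply(fr$mean_perf, fr$hemisphere, sum)))
})

test_that("total brain perfusion applies the missing-lobe rule exactly", {
  expect_equal(
    as.numeric(total_brain_perfusion(c(frontal = 300, temporal = 400,
                                       parietal = 500, occipital = NA))),
    400)
  expect_equal(as.numeric(total_brain_perfusion(
    c(frontal = 7, temporal = 7, parietal = 7, occipital = 7))), 7)
  v <- c(frontal = 310, temporal = 420, parietal = 395, occipital = 287)
  expect_equal(as.numeric(total_brain_perfusion(v)), mean(v))
  expect_error(total_brain_perfusion(c(frontal = 300, temporal = NA,
                                       parietal = NA, occipital = 400)),
               "excluded")
  expect_equal(attr(total_brain_perfusion(
    c(frontal = 300, temporal = 400, parietal = 500, occipital = NA)),
    "missing_lobes"), "occipital")
})

test_that("morphometry composites sum volumes and average thicknesses", {
  morph <- data.frame(
    lobe = rep(c("frontal", "temporal", "parietal", "occipital"), each = 2),
    volume_mm3 = c(5e4, 5e4, 1e5, 1e5, 1.5e5, 1.5e5, 2e5, 2e5),
    thickness_mm = c(2.0, 2.0, 2.2, 2.2, 2.4, 2.4, 2.6, 2.6))
  mc <- morphometry_composites(morph, icv = 1.4e6)
  expect_equal(mc$tbv_mm3, 1.0e6)
  expect_equal(mc$thickness_mm, 2.3)
  expect_equal(mc$icv_mm3, 1.4e6)
  # brute force over the region table
  expect_equal(mc$tbv_mm3, sum(morph$volume_mm3))
  expect_error(morphometry_composites(morph[morph$lobe != "parietal", ]),
               "missing lobe")
})

test_that("BMI and cardiac index follow their standard formulas", {
  expect_equal(bmi(80, 2.0), 20)
  expect_equal(as.numeric(cardiac_index(56, 20)), 2.8)
  expect_error(bmi(80, 0), "positive")
  expect_error(cardiac_index(5, -1), "positive")
  # CI is invariant to unit-consistent rescaling
  co <- 5.6; b <- bmi(80, 2.0)
  expect_equal(as.numeric(cardiac_index(co * 1000, b * 1000)),
               as.numeric(cardiac_index(co, b)))
  expect_equal(attr(cardiac_index(5.6, 1.9, divisor = "bsa"), "divisor"),
               "bsa")
})
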