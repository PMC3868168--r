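#' @title Synthetic phantoms and cohorts
#' @description Generators for every input the pipeline consumes: ASL
#'   control/tag series produced by the same kinetic expression the
#'   quantifier inverts, tissue-probability maps with partial-volume
#'   boundaries, a toy 8-parcel (4 lobes x 2 hemispheres) parcellation,
#'   and participant cohorts with configurable covariate correlations and
#'   a configurable (possibly zero) perfusion effect on each outcome.
#' @name synthetic_data
NULL

#' Specification of a digital ASL phantom
#'
#' A rectangular "brain" (nested boxes: white-matter core wrapped in a
#' gray-matter shell, background outside) on the perfusion acquisition
#' grid: 64 x 64 x 18 voxels at 3 x 3 x 6 mm by default. True CBF defaults
#' to 60 (gray) and 20 (white) mL/100g/min; only the gray/white ratio
#' matters for the tests. Noise is additive i.i.d. Gaussian on every raw
#' frame, in scanner signal units.
#'
#' @param dim Grid dimensions.
#' @param voxdim_mm Voxel sizes (mm).
#' @param cbf_gray,cbf_white True perfusion per tissue (mL/100g/min).
#' @param m0_gray,m0_white Equilibrium signal per tissue (arbitrary units).
#' @param noise_sd Frame noise SD (signal units); 0 = noiseless.
#' @param n_pairs Number of control/tag pairs.
#' @param margin_xy,margin_z Background margin (voxels) around the brain
#'   box in-plane and along the slice axis.
#' @param shell_xy,shell_z Gray-shell thickness (voxels).
#' @return List of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dim = c(64, 64, 18), voxdim_mm = c(3, 3, 6),
                         cbf_gray = 60, cbf_white = 20,
                         m0_gray = 1000, m0_white = 800,
                         noise_sd = 0, n_pairs = 71,
                         margin_xy = 8, margin_z = 2,
                         shell_xy = 4, shell_z = 2) {
  stopifnot(all(dim > 0), noise_sd >= 0, n_pairs >= 1)
  structure(as.list(environment()), class = "phantom_spec")
}

# tissue layout: 0 background, 1 white, 2 gray
phantom_tissue <- function(spec) {
  d <- spec$dim
  tis <- array(0L, dim = d)
  bx <- (spec$margin_xy + 1):(d[1] - spec$margin_xy)
  by <- (spec$margin_xy + 1):(d[2] - spec$margin_xy)
  bz <- (spec$margin_z + 1):(d[3] - spec$margin_z)
  tis[bx, by, bz] <- 2L
  wx <- (spec$margin_xy + spec$shell_xy + 1):(d[1] - spec$margin_xy - spec$shell_xy)
  wy <- (spec$margin_xy + spec$shell_xy + 1):(d[2] - spec$margin_xy - spec$shell_xy)
  wz <- (spec$margin_z + spec$shell_z + 1):(d[3] - spec$margin_z - spec$shell_z)
  tis[wx, wy, wz] <- 1L
  tis
}

#' Noise SD giving a target difference-signal SNR
#'
#' SNR is defined as the gray-matter difference signal divided by the
#' per-frame noise SD.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param params An \code{\link{acquisition_params}}.
#' @param snr Target SNR.
#' @return Noise SD in signal units.
#' @export
noise_sd_for_snr <- function(spec, params, snr) {
  dm_gray <- spec$m0_gray * spec$cbf_gray *
    kinetic_scale(params, "gray", 0L)
  dm_gray / snr
}

#' Simulate an ASL control/tag series from a known CBF map
#'
#' Forward model: control frames sit at the equilibrium signal M0; tag
#' frames at M0 - delta_M, where delta_M is the pulsed-ASL kinetic
#' expression evaluated at the voxel's tissue, true CBF, and
#' slice-specific TI2 — the same shared implementation the quantifier
#' inverts, so quantification of a noiseless series returns the true map
#' to machine precision. Gaussian noise is added independently to every
#' frame. The first frame is a (noisy) control frame and serves as M0.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param params An \code{\link{acquisition_params}}.
#' @param seed Integer seed fixing all randomness.
#' @return List: \code{series} (an \code{\link{asl_series}}),
#'   \code{cbf_true} (3-D map, \code{NA} outside the brain),
#'   \code{m0_true}, \code{tissue} (0/1/2 background/white/gray),
#'   \code{geometry}.
#' @export
simulate_asl_series <- function(spec, params = acquisition_params(),
                                seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  tis <- phantom_tissue(spec)
  d <- spec$dim
  cbf <- array(NA_real_, d)
  cbf[tis == 2L] <- spec$cbf_gray
  cbf[tis == 1L] <- spec$cbf_white
  m0 <- array(0, d)
  m0[tis == 2L] <- spec$m0_gray
  m0[tis == 1L] <- spec$m0_white

  nsl <- d[3]
  sg <- kinetic_scale(params, "gray", seq_len(nsl) - 1L)
  sw <- kinetic_scale(params, "white", seq_len(nsl) - 1L)
  scale <- array(0, d)
  for (k in seq_len(nsl)) {
    sl <- scale[, , k]
    sl[tis[, , k] == 2L] <- sg[k]
    sl[tis[, , k] == 1L] <- sw[k]
    scale[, , k] <- sl
  }
  dm <- m0 * ifelse(is.na(cbf), 0, cbf) * scale

  nf <- 2L * spec$n_pairs
  frames <- array(0, c(d, nf))
  ctrl_idx <- seq(1L, nf, by = 2L)
  frames[, , , ctrl_idx] <- m0
  frames[, , , -ctrl_idx] <- m0 - dm
  if (spec$noise_sd > 0) {
    set.seed(seed)
    frames <- frames + stats::rnorm(length(frames), sd = spec$noise_sd)
  }
  list(series = asl_series(frames, spec$voxdim_mm),
       cbf_true = cbf, m0_true = m0, tissue = tis,
       delta_m_true = dm,
       geometry = vol_geometry(d, spec$voxdim_mm))
}

#' Simulate gray/white tissue-probability maps
#'
#' Posterior-probability maps with smooth partial-volume boundaries,
#' obtained by box-smoothing the phantom's hard tissue indicators: interior
#' voxels are exactly 1 for their tissue, boundary voxels ramp through
#' intermediate probabilities, and gray + white never exceeds 1.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param radius Half-width (voxels) of the smoothing box (default 1).
#' @return List: \code{gray}, \code{white} (probability arrays),
#'   \code{tissue}, \code{geometry}.
#' @export
simulate_probability_maps <- function(spec, radius = 1L) {
  tis <- phantom_tissue(spec)
  smooth_box <- function(ind) {
    out <- array(0, dim(ind))
    cnt <- 0L
    d <- dim(ind)
    for (dx in -radius:radius) for (dy in -radius:radius)
      for (dz in -radius:radius) {
        sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
        sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
        sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
        out <- out + ind[sx, sy, sz]
        cnt <- cnt + 1L
      }
    out / cnt
  }
  list(gray = smooth_box((tis == 2L) + 0),
       white = smooth_box((tis == 1L) + 0),
       tissue = tis,
       geometry = vol_geometry(spec$dim, spec$voxdim_mm))
}

#' Simulate an 8-parcel lobar parcellation
#'
#' Stand-in for a gyral atlas collapsed to lobes: the brain is split into
#' left/right hemispheres at the mid-sagittal plane and into four lobes
#' (frontal, parietal, temporal, occipital) by anterior-to-posterior
#' quarters, giving 8 integer labels with a lookup table. Every brain
#' (gray or white) voxel receives a label; hemispheres are mirror images.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param upsample Integer factor; labels are generated on a grid this many
#'   times finer than the perfusion grid (same field of view), emulating an
#'   anatomical-resolution atlas that must be resampled. Default 1.
#' @return List: \code{values} (integer label array), \code{lut}
#'   (data.frame label/region/lobe/hemisphere), \code{geometry}.
#' @export
simulate_labels <- function(spec, upsample = 1L) {
  upsample <- as.integer(upsample)
  stopifnot(upsample >= 1L)
  d <- spec$dim * upsample
  fine <- phantom_spec(dim = d, voxdim_mm = spec$voxdim_mm / upsample,
                       margin_xy = spec$margin_xy * upsample,
                       margin_z = spec$margin_z * upsample,
                       shell_xy = spec$shell_xy * upsample,
                       shell_z = spec$shell_z * upsample)
  tis <- phantom_tissue(fine)
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  lut <- data.frame(
    label = 1:8,
    region = paste0(rep(c("lh_", "rh_"), each = 4), rep(lobes, 2)),
    lobe = rep(lobes, 2),
    hemisphere = rep(c("left", "right"), each = 4),
    stringsAsFactors = FALSE)
  lab <- array(0L, d)
  brain <- which(tis > 0L, arr.ind = TRUE)
  hemi <- ifelse(brain[, 1] <= d[1] / 2, 0L, 4L)
  # anterior->posterior quarters over the brain's y extent
  yr <- range(brain[, 2])
  qy <- pmin(3L, ((brain[, 2] - yr[1]) * 4L) %/% (yr[2] - yr[1] + 1L))
  lab[brain] <- 1L + qy + hemi
  list(values = lab, lut = lut,
       geometry = vol_geometry(d, spec$voxdim_mm / upsample))
}

#' Specification of a synthetic participant cohort
#'
#' Defaults emulate a cohort of 52 older adults with cardiovascular
#' disease: covariate means/SDs and binary prevalences match that
#' population (e.g., hypertension prevalence 0.423), outcomes are
#' neuropsychological scores on their published scales, and the
#' standardized effect of total brain perfusion on each outcome defaults
#' to 0.35 (set 0 for null calibration). One participant is missing the
#' TMT B score and one the occipital-lobe perfusion composite by default,
#' mirroring the missingness the analysis stage must absorb.
#'
#' @param n Number of participants.
#' @param effect_perfusion True standardized effect of perfusion on every
#'   outcome (scalar, or named per-outcome vector).
#' @param effect_covariates Named standardized effects of block-1
#'   covariates on every outcome.
#' @param latent_cor Named list of pairwise latent correlations between
#'   covariates, as \code{list(c("age", "perfusion_total"), r = ...)}-style
#'   entries; see default.
#' @param prevalence Named binary-condition prevalences.
#' @param n_missing_tmtb,n_missing_occipital Rows with the TMT B score /
#'   occipital perfusion composite set missing.
#' @return List of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n = 52,
                        effect_perfusion = 0.35,
                        effect_covariates = c(age = -0.20, sex = 0.05,
                                              wtar = 0.30, cardiac_index = 0.10,
                                              heart_rate = -0.05, htn = -0.10,
                                              dm = -0.05, afib = -0.05),
                        latent_cor = list(
                          c("age", "perfusion_total", -0.25),
                          c("cardiac_index", "perfusion_total", 0.20),
                          c("heart_rate", "perfusion_total", -0.20),
                          c("htn", "perfusion_total", -0.30),
                          c("age", "htn", 0.20)),
                        prevalence = c(htn = 0.423, dm = 0.096,
                                       afib = 0.096, sex_female = 0.577),
                        n_missing_tmtb = 1L,
                        n_missing_occipital = 1L) {
  stopifnot(n >= 4, all(prevalence >= 0 & prevalence <= 1))
  structure(as.list(environment()), class = "cohort_spec")
}

# covariate scale: name, mean, sd on observed scale
.COVARIATES <- data.frame(
  name = c("age", "wtar", "cardiac_index", "heart_rate",
           "perfusion_total"),
  mean = c(65.73, 110.17, 2.80, 64.62, 376.45),
  sd = c(8.99, 7.52, 0.58, 8.83, 54.53),
  stringsAsFactors = FALSE)

.OUTCOMES <- data.frame(
  name = c("mmse", "rbans_immediate", "rbans_visuospatial", "rbans_language",
           "rbans_attention", "rbans_delayed", "rbans_total",
           "tmt_a", "tmt_b"),
  mean = c(29.06, 105.60, 104.83, 103.88, 105.12, 103.40, 106.40,
           11.98, 11.59),
  sd = c(1.46, 13.48, 15.56, 11.75, 13.32, 12.489, 12.80, 2.55, 2.74),
  stringsAsFactors = FALSE)

# assemble the latent correlation matrix from the spec's pair list
.latent_corr <- function(spec, vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (e in spec$latent_cor) {
    a <- e[[1]]; b <- e[[2]]; r <- as.numeric(e[[3]])
    if (a %in% vars && b %in% vars) R[a, b] <- R[b, a] <- r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent correlation matrix is not positive semidefinite")
  R
}

# population covariance of the z-scored observed covariates given the
# latent normal structure (binary b = 1{Z > tau}; cov(X, zb) = rho*phi(tau)/
# sqrt(p(1-p)); binaries are pairwise latent-independent by default)
.zcov <- function(R, binary, tau, p) {
  Z <- R
  for (b in names(binary)) {
    for (v in rownames(R)) {
      if (v == b) next
      if (v %in% names(binary)) {
        if (R[v, b] != 0)
          stop("latent correlation between two binary covariates is not supported")
        Z[v, b] <- Z[b, v] <- 0
      } else {
        Z[v, b] <- Z[b, v] <- R[v, b] * stats::dnorm(tau[b]) /
          sqrt(p[b] * (1 - p[b]))
      }
    }
  }
  Z
}

#' Simulate a participant cohort with known regression structure
#'
#' Continuous covariates and the latent variables behind the binary
#' conditions are drawn from a multivariate normal with the specified
#' correlations (binaries by thresholding the latents at their prevalence
#' quantile). Each outcome is a linear predictor on the
#' population-z-scored covariates — perfusion carrying the specified
#' standardized effect — plus a Gaussian residual scaled so the outcome
#' has unit population variance before mapping onto its published
#' mean/SD scale. The true parameters are attached for recovery tests.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Integer seed.
#' @return Data.frame of class \code{cohort_table} with one row per
#'   participant; attribute \code{truth} records the generating
#'   parameters.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  cont <- .COVARIATES$name
  bins <- c("htn", "dm", "afib", "sex_female")
  vars <- c(cont, bins)
  R <- .latent_corr(spec, vars)
  L <- chol(R + diag(1e-12, nrow(R)))
  Zlat <- matrix(stats::rnorm(n * length(vars)), n) %*% L
  colnames(Zlat) <- vars

  p <- spec$prevalence[bins]
  names(p) <- bins
  tau <- stats::qnorm(1 - p)
  obs <- as.data.frame(Zlat[, cont, drop = FALSE])
  for (v in cont) {
    sc <- .COVARIATES[.COVARIATES$name == v, ]
    obs[[v]] <- sc$mean + sc$sd * obs[[v]]
  }
  for (b in bins) obs[[b]] <- as.integer(Zlat[, b] > tau[b])
  obs$sex <- ifelse(obs$sex_female == 1L, 1L, -1L)

  # population z-scores of the model covariates
  zs <- function(v) {
    if (v == "sex") {
      pf <- p["sex_female"]
      (obs$sex - (2 * pf - 1)) / (2 * sqrt(pf * (1 - pf)))
    } else if (v %in% bins) {
      (obs[[v]] - p[v]) / sqrt(p[v] * (1 - p[v]))
    } else {
      sc <- .COVARIATES[.COVARIATES$name == v, ]
      (obs[[v]] - sc$mean) / sc$sd
    }
  }
  model_vars <- c("age", "sex", "wtar", "cardiac_index", "heart_rate",
                  "htn", "dm", "afib", "perfusion_total")
  Zmod <- vapply(model_vars, zs, numeric(n))

  # exact population covariance of the z-scored design (sex is an affine
  # map of sex_female, so shares its covariance rows)
  map <- ifelse(model_vars == "sex", "sex_female", model_vars)
  Zcov <- .zcov(R, p, tau, p)[map, map]
  dimnames(Zcov) <- list(model_vars, model_vars)

  eff_cov <- spec$effect_covariates[setdiff(model_vars, "perfusion_total")]
  eff_cov[is.na(eff_cov)] <- 0
  truth <- list()
  for (i in seq_len(nrow(.OUTCOMES))) {
    oc <- .OUTCOMES[i, ]
    bstar <- if (length(spec$effect_perfusion) == 1L) spec$effect_perfusion
             else spec$effect_perfusion[[oc$name]]
    cvec <- c(eff_cov, perfusion_total = unname(bstar))[model_vars]
    cvec[is.na(cvec)] <- 0
    v_lp <- drop(cvec %*% Zcov %*% cvec)
    if (v_lp >= 1)
      stop("effect sizes imply explained variance >= 1 for ", oc$name)
    ystd <- drop(Zmod %*% cvec) + stats::rnorm(n, sd = sqrt(1 - v_lp))
    obs[[oc$name]] <- oc$mean + oc$sd * ystd
    truth[[oc$name]] <- list(beta_perfusion = unname(bstar),
                             beta_covariates = cvec[names(cvec) !=
                                                      "perfusion_total"],
                             resid_sd = sqrt(1 - v_lp))
  }
  obs$mmse <- pmin(pmax(obs$mmse, 0), 30)

  # lobar perfusion composites scatter around the total
  for (lb in c("frontal", "temporal", "parietal", "occipital"))
    obs[[paste0("perfusion_", lb)]] <-
      obs$perfusion_total + stats::rnorm(n, sd = 15)

  # structural composites on their published scales
  obs$icv <- stats::rnorm(n, 1.45e6, 1.3e5)
  obs$tbv <- 447348.79 + 47746.92 *
    (0.5 * zs("perfusion_total") + stats::rnorm(n, sd = sqrt(1 - 0.25)))
  obs$thickness <- 2.42 + 0.10 * stats::rnorm(n)

  if (spec$n_missing_tmtb > 0)
    obs$tmt_b[sample(n, spec$n_missing_tmtb)] <- NA_real_
  if (spec$n_missing_occipital > 0)
    obs$perfusion_occipital[sample(n, spec$n_missing_occipital)] <- NA_real_

  obs$sex_female <- NULL
  rownames(obs) <- NULL
  attr(obs, "truth") <- truth
  class(obs) <- c("cohort_table", "data.frame")
  obs
}
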