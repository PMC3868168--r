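#' Pulse-timing and tissue constants for pulsed-ASL quantification
#'
#' Bundles every constant entering the PICORE Q2TIPS perfusion expression:
#' sequence timing (TR, TE, TI1, TI2 and its per-slice increment), inversion
#' efficiency, the longitudinal relaxation times of arterial blood and of
#' gray/white tissue, the vascular-to-tissue water-exchange lag, and the
#' blood--brain water partition coefficient.
#'
#' Defaults are the acquisition this package models: a 3T PICORE Q2TIPS
#' protocol with TR = 2500 ms, TI1 = 700 ms, TI2 = 1800 ms at the first
#' slice, inversion efficiency 0.95, arterial T1 = 1664 ms, tissue
#' T1 = 1300 ms (gray) / 1000 ms (white), exchange lag 1000 ms and
#' lambda = 0.9 mL/g. The per-slice TI2 increment is not part of the
#' protocol's reference constants; the default spreads the post-TI2 readout
#' window (TR - TI2) evenly over the 9 slices acquired per excitation.
#'
#' @param tr_ms Repetition time (ms).
#' @param te_ms Echo time (ms).
#' @param ti1_ms Inversion-to-saturation interval TI1, the tagged-bolus
#'   temporal width (ms).
#' @param ti2_base_ms Inversion-to-readout interval TI2 for the first
#'   slice (ms).
#' @param slice_dt_ms Increment added to TI2 per slice position (ms).
#' @param alpha Inversion efficiency in (0, 1]; 1 is perfect inversion.
#' @param t1_arterial_ms Arterial blood longitudinal relaxation time (ms).
#' @param t1_tissue_gray_ms,t1_tissue_white_ms Tissue longitudinal
#'   relaxation times (ms).
#' @param t_ex_ms Vascular-to-interstitial water-exchange lag (ms).
#' @param lambda_ml_per_g Blood--brain water partition coefficient (mL/g).
#' @return An object of class \code{acquisition_params}.
#' @examples
#' p <- acquisition_params()
#' slice_ti2(p, 0:3)
#' @export
acquisition_params <- function(tr_ms = 2500, te_ms = 16,
                               ti1_ms = 700, ti2_base_ms = 1800,
                               slice_dt_ms = (tr_ms - ti2_base_ms) / 9,
                               alpha = 0.95,
                               t1_arterial_ms = 1664,
                               t1_tissue_gray_ms = 1300,
                               t1_tissue_white_ms = 1000,
                               t_ex_ms = 1000,
                               lambda_ml_per_g = 0.9) {
  p <- list(tr_ms = tr_ms, te_ms = te_ms, ti1_ms = ti1_ms,
            ti2_base_ms = ti2_base_ms, slice_dt_ms = slice_dt_ms,
            alpha = alpha, t1_arterial_ms = t1_arterial_ms,
            t1_tissue_gray_ms = t1_tissue_gray_ms,
            t1_tissue_white_ms = t1_tissue_white_ms,
            t_ex_ms = t_ex_ms, lambda_ml_per_g = lambda_ml_per_g)
  times <- c("tr_ms", "te_ms", "ti1_ms", "ti2_base_ms", "t1_arterial_ms",
             "t1_tissue_gray_ms", "t1_tissue_white_ms", "t_ex_ms",
             "lambda_ml_per_g")
  for (nm in times) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  if (!is.numeric(slice_dt_ms) || slice_dt_ms < 0)
    stop("'slice_dt_ms' must be nonnegative")
  if (!(alpha > 0 && alpha <= 1))
    stop("'alpha' must lie in (0, 1]")
  if (ti1_ms >= ti2_base_ms)
    stop("'ti1_ms' must be smaller than 'ti2_base_ms'")
  structure(p, class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Pulsed-ASL acquisition parameters\n")
  cat(sprintf("  TR %g ms, TE %g ms, TI1 %g ms, TI2 %g ms (+%.2f ms/slice)\n",
              x$tr_ms, x$te_ms, x$ti1_ms, x$ti2_base_ms, x$slice_dt_ms))
  cat(sprintf("  alpha %g, T1a %g ms, T1 gray %g ms, T1 white %g ms\n",
              x$alpha, x$t1_arterial_ms, x$t1_tissue_gray_ms,
              x$t1_tissue_white_ms))
  cat(sprintf("  Tex %g ms, lambda %g mL/g\n", x$t_ex_ms, x$lambda_ml_per_g))
  invisible(x)
}

#' Slice-specific inversion-to-readout interval
#'
#' Echo-planar slices are read out sequentially, so the effective TI2 grows
#' with slice position. Ignoring this (a zero increment) produces a
#' progressive underestimation of perfusion with advancing slice position,
#' because the tag has decayed further than the model assumes.
#'
#' @param params An \code{\link{acquisition_params}} object.
#' @param slice_index 0-based slice position(s) along the slice axis.
#' @return TI2 in ms, \code{ti2_base_ms + slice_index * slice_dt_ms},
#'   vectorized over \code{slice_index}.
#' @export
slice_ti2 <- function(params, slice_index) {
  stopifnot(inherits(params, "acquisition_params"))
  if (any(slice_index < 0) || any(slice_index != floor(slice_index)))
    stop("'slice_index' must be a nonnegative integer (0-based)")
  params$ti2_base_ms + slice_index * params$slice_dt_ms
}
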