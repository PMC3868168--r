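#' @title Participant-level perfusion and morphometry composites
#' @description Reduces masked perfusion maps and per-region morphometry
#'   tables to the lobar and whole-brain composites entered into the
#'   regression models.
#' @name composites
NULL

#' Read a region lookup table
#'
#' Delimited text mapping integer labels to (region, lobe, hemisphere),
#' in the style of a FreeSurfer color lookup table restricted to the
#' columns this package needs.
#'
#' @param path Tab- or comma-delimited file with columns \code{label},
#'   \code{region}, \code{lobe}, \code{hemisphere}.
#' @return A data.frame.
#' @export
read_label_lut <- function(path) {
  lut <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  need <- c("label", "region", "lobe", "hemisphere")
  if (!all(need %in% names(lut)))
    stop("lookup table must have columns: ", paste(need, collapse = ", "))
  lut
}

#' Per-region perfusion summaries
#'
#' For every region of the parcellation, the mean and SD of perfusion over
#' voxels whose value lies inside the physiological band
#' \code{[low, high]} (inclusive at both ends; default 1--100 mL/100g/min).
#' Voxels flagged invalid during quantification (\code{NA}) or outside the
#' band are excluded. A region with no surviving voxel is reported with
#' \code{NA} mean/SD and count 0, never as zero perfusion.
#'
#' @param perf 3-D perfusion array (masked; \code{NA} outside brain).
#' @param labels 3-D integer label array on the same grid.
#' @param lut Lookup data.frame (\code{label}, \code{region}, \code{lobe},
#'   \code{hemisphere}); see \code{\link{read_label_lut}}.
#' @param low,high Inclusive bounds of admitted perfusion values.
#' @return Data.frame of class \code{region_table}: one row per lookup
#'   region with \code{mean_perf}, \code{sd_perf}, \code{n_voxels}.
#' @export
region_stats <- function(perf, labels, lut, low = 1, high = 100) {
  if (!identical(dim(perf), dim(labels)))
    stop("geometry mismatch: labels are not on the perfusion grid")
  if (low >= high) stop("'low' must be smaller than 'high'")
  bad <- setdiff(unique(as.integer(labels)), c(0L, lut$label))
  if (length(bad))
    stop("labels absent from lookup table: ", paste(bad, collapse = ", "))
  keep <- !is.na(perf) & perf >= low & perf <= high & labels > 0
  v <- perf[keep]
  l <- as.integer(labels)[keep]
  agg_n <- tapply(v, l, length)
  agg_mean <- tapply(v, l, mean)
  agg_sd <- tapply(v, l, stats::sd)
  out <- lut[, c("label", "region", "lobe", "hemisphere")]
  key <- as.character(out$label)
  out$n_voxels <- ifelse(is.na(agg_n[key]), 0L, agg_n[key])
  out$mean_perf <- as.numeric(agg_mean[key])
  out$sd_perf <- as.numeric(agg_sd[key])
  rownames(out) <- NULL
  class(out) <- c("region_table", "data.frame")
  out
}

#' Lobar perfusion composites
#'
#' Aggregates region summaries to one value per lobe: regions are combined
#' within each (lobe, hemisphere), then the two hemispheres are averaged.
#' The default aggregation is the voxel-count-weighted mean of region means
#' (equal to the lobe-level voxel mean); \code{agg = "sum"} instead sums
#' the region means. A lobe present in only one hemisphere gets that
#' hemisphere's value and is flagged.
#'
#' @param table A \code{\link{region_stats}} table (needs \code{lobe},
#'   \code{hemisphere}, \code{mean_perf}, \code{n_voxels}).
#' @param agg \code{"wmean"} (default) or \code{"sum"}.
#' @return Data.frame: \code{lobe}, \code{perfusion}, \code{n_hemispheres}.
#' @export
lobar_perfusion <- function(table, agg = c("wmean", "sum")) {
  agg <- match.arg(agg)
  if (!nrow(table)) stop("empty region table")
  t2 <- table[!is.na(table$mean_perf) & table$n_voxels > 0, ]
  hemi_val <- function(df) {
    if (agg == "wmean") sum(df$mean_perf * df$n_voxels) / sum(df$n_voxels)
    else sum(df$mean_perf)
  }
  lobes <- unique(table$lobe)
  res <- lapply(lobes, function(lb) {
    sub <- t2[t2$lobe == lb, ]
    if (!nrow(sub)) return(data.frame(lobe = lb, perfusion = NA_real_,
                                      n_hemispheres = 0L))
    hv <- vapply(split(sub, sub$hemisphere), hemi_val, numeric(1))
    data.frame(lobe = lb, perfusion = mean(hv),
               n_hemispheres = length(hv))
  })
  out <- do.call(rbind, res)
  if (any(out$n_hemispheres == 1L))
    warning("lobe(s) with a single hemisphere: ",
            paste(out$lobe[out$n_hemispheres == 1L], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Total brain perfusion with the missing-lobe rule
#'
#' The whole-brain composite is the mean of the four hemisphere-averaged
#' lobar values. If exactly one lobe is missing the mean of the remaining
#' lobes is used (and the missingness attached as an attribute); with two
#' or more lobes missing the participant cannot be summarized and an error
#' naming the missing lobes is raised.
#'
#' @param lobar Named numeric vector of the four lobar perfusion values
#'   (frontal, temporal, parietal, occipital), \code{NA} = missing, or the
#'   data.frame returned by \code{\link{lobar_perfusion}}.
#' @return Scalar mean of the available lobes; attribute
#'   \code{missing_lobes} lists any lobe that was dropped.
#' @export
total_brain_perfusion <- function(lobar) {
  if (is.data.frame(lobar)) {
    v <- lobar$perfusion
    names(v) <- lobar$lobe
    lobar <- v
  }
  if (length(lobar) != 4L)
    stop("expected four lobar values (frontal, temporal, parietal, occipital)")
  miss <- names(lobar)[is.na(lobar)]
  if (length(miss) >= 2L)
    stop("participant excluded: ", length(miss), " lobes missing (",
         paste(miss, collapse = ", "), ")")
  out <- mean(lobar, na.rm = TRUE)
  attr(out, "missing_lobes") <- miss
  out
}

#' Morphometry composites: total brain volume and mean thickness
#'
#' Total brain volume (TBV) is the sum of the four lobar gray-matter
#' volumes; total cortical thickness is the unweighted mean of the four
#' lobar mean thicknesses. Lobar values are built from a per-region
#' morphometry table by summing region volumes and averaging region
#' thicknesses over both hemispheres. Intracranial volume is carried
#' through unchanged for use as a covariate.
#'
#' @param morph Data.frame with columns \code{lobe}, \code{volume_mm3},
#'   \code{thickness_mm} (one row per region; hemispheres as extra rows).
#' @param icv Intracranial volume (mm^3).
#' @return List: \code{tbv_mm3}, \code{thickness_mm}, \code{icv_mm3},
#'   plus per-lobe volume and thickness vectors.
#' @export
morphometry_composites <- function(morph, icv = NA_real_) {
  lobes <- c("frontal", "temporal", "parietal", "occipital")
  if (!all(lobes %in% morph$lobe))
    stop("participant flagged: missing lobe(s) ",
         paste(setdiff(lobes, morph$lobe), collapse = ", "))
  vol <- vapply(lobes, function(lb)
    sum(morph$volume_mm3[morph$lobe == lb]), numeric(1))
  thk <- vapply(lobes, function(lb)
    mean(morph$thickness_mm[morph$lobe == lb]), numeric(1))
  list(tbv_mm3 = sum(vol), thickness_mm = mean(thk), icv_mm3 = icv,
       lobar_volume_mm3 = vol, lobar_thickness_mm = thk)
}

#' Body mass index
#'
#' @param mass_kg Body mass (kg).
#' @param height_m Height (m).
#' @return mass / height^2 (kg/m^2).
#' @export
bmi <- function(mass_kg, height_m) {
  if (any(height_m <= 0) || any(mass_kg <= 0))
    stop("mass and height must be positive")
  mass_kg / height_m^2
}

#' Cardiac index
#'
#' Cardiac output normalized by body size. The conventional divisor is
#' body-surface area; dividing by BMI is also offered and is the package
#' default for compatibility with studies that normalized by BMI.
#'
#' @param cardiac_output Cardiac output (L/min).
#' @param body_size BMI (kg/m^2) or body-surface area (m^2), matching
#'   \code{divisor}.
#' @param divisor \code{"bmi"} (default) or \code{"bsa"}.
#' @return cardiac_output / body_size.
#' @export
cardiac_index <- function(cardiac_output, body_size,
                          divisor = c("bmi", "bsa")) {
  divisor <- match.arg(divisor)
  if (any(body_size <= 0)) stop("body size divisor must be positive")
  out <- cardiac_output / body_size
  attr(out, "divisor") <- divisor
  out
}
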