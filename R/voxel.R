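## Voxel-based metrics: intrinsic connectivity (IC), local correlation
## (LCOR) and fractional amplitude of low-frequency fluctuations (fALFF),
## plus aggregation of voxel maps to atlas regions. Self-correlation is
## excluded from the IC and LCOR sums: including the constant 1 would
## inflate both without adding information.

#' fALFF of a single timeseries
#'
#' Ratio of the root-mean-square of the band-passed, demeaned series to the
#' RMS of the demeaned (but unfiltered) series. Intended to run on
#' confound-regressed data; the denominator is deliberately the pre-filter
#' series.
#'
#' @param x Numeric timeseries.
#' @param tr Repetition time (s).
#' @param f_lo,f_hi Passband in Hz.
#' @return fALFF in `[0, 1]` (up to filter tolerance), or `NA` for a
#'   zero-variance series.
#' @export
falff_series <- function(x, tr, f_lo = 0.008, f_hi = 0.09) {
  x <- x - mean(x)
  denom <- sqrt(mean(x^2))
  if (denom == 0) return(NA_real_)
  xf <- bandpass(x, tr, f_lo, f_hi)
  sqrt(mean(xf^2)) / denom
}

#' Intrinsic connectivity map
#'
#' IC of a voxel is the root-mean-square of its correlations with every
#' other in-mask voxel. Each voxel series is z-scored over time and the
#' correlation structure is evaluated in a rank-`min(n_components, rank)`
#' SVD subspace of the z-scored voxel-by-time matrix (truncated
#' reconstruction); with full rank this equals the direct computation.
#'
#' @param panel A `voxel_panel`.
#' @param n_components SVD rank (default 64).
#' @return 3-D array of class `voxel_metric_map`; background voxels `NA`.
#' @export
intrinsic_connectivity <- function(panel, n_components = 64L) {
  fl <- flatten_voxels(panel)
  v <- ncol(fl$ts)
  if (v < 2) stop("intrinsic connectivity needs at least 2 in-mask voxels")
  z <- scale(fl$ts)
  z[is.na(z)] <- 0
  k <- min(n_components, dim(z))
  sv <- svd(z, nu = k, nv = k)
  zk <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  r <- suppressWarnings(stats::cor(zk))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 0
  ic <- sqrt(rowSums(r2) / (v - 1))
  map_from_values(panel, ic)
}

#' Local correlation map
#'
#' LCOR of a voxel is the Gaussian-distance-weighted average of its
#' correlations with the other in-mask voxels, with kernel full width at
#' half maximum `fwhm_mm` (so `sigma = fwhm / (2 sqrt(2 ln 2))`) and
#' distances measured in mm between voxel centres.
#'
#' @param panel A `voxel_panel`.
#' @param fwhm_mm Neighbourhood FWHM in mm (default 25).
#' @return 3-D array of class `voxel_metric_map`; a voxel with no neighbour
#'   of weight above 1e-6 is `NA` with a warning.
#' @export
local_correlation <- function(panel, fwhm_mm = 25) {
  fl <- flatten_voxels(panel)
  v <- ncol(fl$ts)
  if (v < 2) stop("local correlation needs at least 2 in-mask voxels")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(fl$coords))^2
  w <- exp(-d2 / (2 * sigma^2))
  diag(w) <- 0
  w[w <= 1e-6] <- 0
  r <- suppressWarnings(stats::cor(fl$ts))
  r[!is.finite(r)] <- 0
  wsum <- rowSums(w)
  lcor <- rowSums(w * r) / wsum
  if (any(wsum == 0)) {
    warning(sum(wsum == 0), " voxel(s) have no in-mask neighbour within the ",
            "kernel support; set missing")
    lcor[wsum == 0] <- NA_real_
  }
  map_from_values(panel, lcor)
}

#' fALFF map
#'
#' Voxelwise fALFF (see [falff_series()]): band-limited RMS over broadband
#' RMS, both after demeaning. Expects confound-regressed input; the
#' denominator uses the unfiltered series.
#'
#' @param panel A `voxel_panel` (confound-regressed).
#' @param f_lo,f_hi Passband in Hz.
#' @return 3-D array of class `voxel_metric_map`; zero-variance voxels `NA`.
#' @export
falff <- function(panel, f_lo = 0.008, f_hi = 0.09) {
  fl <- flatten_voxels(panel)
  vals <- apply(fl$ts, 2, falff_series, tr = panel$tr, f_lo = f_lo,
                f_hi = f_hi)
  map_from_values(panel, vals)
}

map_from_values <- function(panel, values) {
  dims <- dim(panel$data)[1:3]
  m <- array(NA_real_, dim = dims)
  m[which(panel$parcellation > 0)] <- values
  class(m) <- c("voxel_metric_map", class(m))
  m
}

#' Aggregate a voxel metric map to atlas regions
#'
#' ROI value = mean over the region's non-missing voxels; a region with no
#' (non-missing) voxels is reported missing.
#'
#' @param map A `voxel_metric_map` (3-D array).
#' @param parcellation Integer 3-D array of ROI labels (0 = background).
#' @param atlas An `atlas_table`.
#' @param metric Name recorded in the output `metric` column.
#' @param subject Name recorded in the output `subject` column.
#' @return Long data frame (`subject`, `roi`, `metric`, `value`) with one
#'   row per atlas region present in the parcellation.
#' @export
aggregate_to_rois <- function(map, parcellation, atlas, metric = "IC",
                              subject = "sub-001") {
  validate_atlas(atlas)
  labs <- setdiff(unique(as.vector(parcellation)), 0L)
  unknown <- setdiff(labs, atlas$roi_id)
  if (length(unknown))
    stop("parcellation labels absent from the atlas: ",
         paste(unknown, collapse = ", "))
  vals <- vapply(labs, function(l) {
    v <- map[parcellation == l]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(subject = subject,
             roi = atlas$name[match(labs, atlas$roi_id)],
             metric = metric, value = vals,
             stringsAsFactors = FALSE)
}

#' All three voxel metrics aggregated to regions
#'
#' Convenience wrapper running [intrinsic_connectivity()],
#' [local_correlation()] and [falff()] on one voxel session and aggregating
#' each to atlas regions.
#'
#' @inheritParams intrinsic_connectivity
#' @inheritParams local_correlation
#' @param atlas An `atlas_table`.
#' @param subject Subject label for the output rows.
#' @param band fALFF passband (Hz).
#' @return Long data frame (`subject`, `roi`, `metric`, `value`) with
#'   metrics `IC`, `LCOR`, `fALFF`.
#' @export
compute_voxel_metrics <- function(panel, atlas, n_components = 64L,
                                  fwhm_mm = 25, band = c(0.008, 0.09),
                                  subject = "sub-001") {
  ic <- intrinsic_connectivity(panel, n_components)
  lc <- local_correlation(panel, fwhm_mm)
  fa <- falff(panel, band[1], band[2])
  rbind(
    aggregate_to_rois(ic, panel$parcellation, atlas, "IC", subject),
    aggregate_to_rois(lc, panel$parcellation, atlas, "LCOR", subject),
    aggregate_to_rois(fa, panel$parcellation, atlas, "fALFF", subject)
  )
}
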