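## Synthetic two-cohort BOLD generator with known lateralisation ground truth.
##
## Signal model (per subject s):
##   global latent  c_s(t)   ~ band-limited Gaussian process, unit sd
##   pair latents   h_sp(t)  ~ band-limited Gaussian process, unit sd
##   ROI i (pair p, hemisphere H):
##     y_i(t) = m_bp[i] * ( a * g_conn[i] * c_s(t) + b * h_sp(t) ) + noise_sd * eps(t)
## where a, b are the baseline global/pair loadings, g_conn multiplies the
## global-signal loading on the hemisphere favoured by a "connectivity"
## effect, and m_bp multiplies the whole band-limited part on the hemisphere
## favoured by a "band_power" effect.  "coherence" effects act on the
## within-ROI voxel mixing weight and are consumed by simulate_voxel_session.
## Multipliers are calibrated by simulation so that a requested effect size is
## the expected paired Cohen's d of the downstream L-R contrast.

BASE_GLOBAL_LOADING <- 0.6
BASE_PAIR_LOADING <- 0.6
BASE_COHERENCE <- 0.7

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: cohort size, run
#' length, repetition time, atlas shape, implanted lateralisation effects,
#' noise level, implanted motion-outlier frames and the master seed.
#'
#' Defaults mirror a typical single-site healthy-control resting-state
#' cohort: 102 subjects, TR 2 s, a 10-minute run (300 frames), and a
#' 66-pair (132-region) atlas. A second cohort emulating a multi-site
#' public-database sample would use `n_subjects = 86, tr = 3`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_timepoints Frames per run (>= 16).
#' @param tr Repetition time in seconds (> 0).
#' @param n_pairs,n_unpaired Atlas shape (see [make_toy_atlas()]).
#' @param effects `NULL`, or a data frame with columns `pair_id`,
#'   `family` (one of `"connectivity"`, `"coherence"`, `"band_power"`),
#'   `direction` (`"left"` or `"right"`) and `effect_size` (target paired
#'   Cohen's d of the downstream L-R contrast, >= 0).
#' @param noise_sd White-noise standard deviation added to each ROI series.
#' @param outlier_frames `NULL`, or a data frame with columns `subject`,
#'   `frame` (1-based) naming frames at which [simulate_motion()] implants
#'   spikes.
#' @param demographics Named list of cohort demographic parameters:
#'   `age_mean`, `age_sd`, `female_frac`, `edu_mean`, `edu_sd`, `mmse_mean`,
#'   `mmse_sd`.
#' @param band Passband (Hz) of the latent band-limited processes.
#' @param coherence_base Baseline within-region voxel mixing weight `w`
#'   in `[0, 1]` used by [simulate_voxel_session()]; pairwise within-region
#'   voxel correlation is `w^2`.
#' @param seed Master seed (integer); one RNG stream per subject is derived
#'   from it by fixed ordinal, so subject subsets are reproducible.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 102L, n_timepoints = 300L,
                              tr = 2, n_pairs = 66L, n_unpaired = 0L,
                              effects = NULL, noise_sd = 1,
                              outlier_frames = NULL,
                              demographics = list(
                                age_mean = 66, age_sd = 7.5,
                                female_frac = 0.68,
                                edu_mean = 16.15, edu_sd = 3.0,
                                mmse_mean = 28.58, mmse_sd = 1.1),
                              band = c(0.008, 0.09),
                              coherence_base = 0.7,
                              seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("'n_subjects' must be >= 2")
  if (is.na(n_timepoints) || n_timepoints < 16L)
    stop("'n_timepoints' must be >= 16")
  if (!is.numeric(tr) || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a positive number of seconds")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive")
  if (!is.null(effects)) {
    req <- c("pair_id", "family", "direction", "effect_size")
    if (!all(req %in% names(effects)))
      stop("'effects' needs columns: ", paste(req, collapse = ", "))
    if (!all(effects$family %in% c("connectivity", "coherence", "band_power")))
      stop("unknown effect family; use connectivity, coherence or band_power")
    if (!all(effects$direction %in% c("left", "right")))
      stop("effect direction must be 'left' or 'right'")
    if (any(effects$effect_size < 0))
      stop("effect sizes must be nonnegative")
    if (any(effects$pair_id > n_pairs | effects$pair_id < 1))
      stop("effects reference pair_ids outside the atlas (1..", n_pairs, ")")
    if (anyDuplicated(effects[, c("pair_id", "family")]))
      stop("at most one effect per pair and family")
  }
  if (!is.null(outlier_frames)) {
    if (!all(c("subject", "frame") %in% names(outlier_frames)))
      stop("'outlier_frames' needs columns subject, frame")
    if (any(outlier_frames$frame > n_timepoints | outlier_frames$frame < 1))
      stop("outlier frame index beyond the run length (", n_timepoints, ")")
    if (any(outlier_frames$subject > n_subjects | outlier_frames$subject < 1))
      stop("outlier subject index beyond the cohort size")
  }
  if (!is.numeric(coherence_base) || coherence_base < 0 || coherence_base > 1)
    stop("'coherence_base' must lie in [0, 1]")
  if (band[1] <= 0 || band[2] <= band[1])
    stop("'band' must satisfy 0 < f_lo < f_hi")
  if (band[2] >= 1 / (2 * tr))
    stop("band upper edge must lie below the Nyquist frequency 1/(2*TR) = ",
         signif(1 / (2 * tr), 4), " Hz for TR = ", tr, " s")
  structure(list(n_subjects = n_subjects, n_timepoints = n_timepoints,
                 tr = tr, n_pairs = as.integer(n_pairs),
                 n_unpaired = as.integer(n_unpaired),
                 effects = effects, noise_sd = noise_sd,
                 outlier_frames = outlier_frames,
                 demographics = demographics,
                 band = band, coherence_base = coherence_base,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Fixed per-subject, per-purpose RNG stream derived from the master seed.
## Kept below 2^31 - 1 so it is always a valid integer seed.
stream_seed <- function(master, stream, ordinal) {
  (abs(as.numeric(master)) * 100003 + stream * 7919 + ordinal * 104729) %%
    2147483647
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Band-limited unit-variance Gaussian process, generated in the frequency
## domain: independent complex-Gaussian coefficients on the DFT bins whose
## frequency falls inside [f_lo, f_hi], conjugate-symmetrised, inverted.
band_limited_series <- function(n_t, tr, f_lo = 0.008, f_hi = 0.09) {
  freqs <- seq_len(floor(n_t / 2)) / (n_t * tr)
  keep <- which(freqs >= f_lo & freqs <= f_hi)
  if (!length(keep))
    stop("no DFT bin falls inside the requested band; lengthen the run")
  spec <- complex(real = rep(0, n_t), imaginary = rep(0, n_t))
  coef <- complex(real = stats::rnorm(length(keep)),
                  imaginary = stats::rnorm(length(keep)))
  spec[keep + 1L] <- coef
  spec[n_t + 1L - keep] <- Conj(coef)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n_t
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band-limited draw")
  (x - mean(x)) / s
}

## ---- Effect-size calibration ------------------------------------------------
## Maps a target downstream Cohen's d to a generator multiplier by simulating
## the L-R contrast on a small surrogate at a multiplier grid and
## interpolating. Calibrated once per (family, run length, TR, noise level)
## and cached for the session; the calibration RNG is fixed, so the mapping
## is deterministic and independent of the cohort seed.
.calibration_cache <- new.env(parent = emptyenv())

calibration_grid <- c(1, 1.05, 1.1, 1.2, 1.35, 1.6, 2, 2.8, 4, 6)

calibrate_multiplier <- function(family, target_d, n_t, tr, noise_sd,
                                 band = c(0.008, 0.09), n_cal = 300L,
                                 coh_base = BASE_COHERENCE) {
  if (target_d == 0) return(1)
  key <- paste(family, n_t, signif(tr, 8), signif(noise_sd, 8),
               band[1], band[2], n_cal, signif(coh_base, 8), sep = "|")
  if (is.null(.calibration_cache[[key]])) {
    .calibration_cache[[key]] <- with_seed(20260921, {
      d_at <- vapply(calibration_grid, function(m) {
        contrast_d(family, m, n_t, tr, noise_sd, band, n_cal, coh_base)
      }, numeric(1))
      d_at <- cummax(d_at)  # enforce monotone grid for interpolation
      list(grid = calibration_grid, d = d_at)
    })
  }
  cal <- .calibration_cache[[key]]
  if (target_d >= max(cal$d)) {
    warning("target effect size ", target_d,
            " beyond the calibrated range; using the largest multiplier")
    return(max(cal$grid))
  }
  stats::approx(cal$d, cal$grid, xout = target_d, ties = "ordered")$y
}

## Simulated Cohen's d of the L-R contrast for one pair at multiplier m.
contrast_d <- function(family, m, n_t, tr, noise_sd, band, n_cal,
                       coh_base = BASE_COHERENCE) {
  a <- BASE_GLOBAL_LOADING; b <- BASE_PAIR_LOADING
  diffs <- vapply(seq_len(n_cal), function(i) {
    g <- band_limited_series(n_t, tr, band[1], band[2])
    h <- band_limited_series(n_t, tr, band[1], band[2])
    switch(family,
      band_power = {
        yl <- m * (a * g + b * h) + noise_sd * stats::rnorm(n_t)
        yr <- (a * g + b * h) + noise_sd * stats::rnorm(n_t)
        falff_series(yl, tr, band[1], band[2]) -
          falff_series(yr, tr, band[1], band[2])
      },
      connectivity = {
        nbg <- 24L
        bg <- vapply(seq_len(nbg), function(j)
          a * g + b * band_limited_series(n_t, tr, band[1], band[2]) +
            noise_sd * stats::rnorm(n_t), numeric(n_t))
        yl <- m * a * g + b * h + noise_sd * stats::rnorm(n_t)
        yr <- a * g + b * h + noise_sd * stats::rnorm(n_t)
        zl <- atanh(pmin(pmax(stats::cor(yl, bg), -1 + 1e-7), 1 - 1e-7))
        zr <- atanh(pmin(pmax(stats::cor(yr, bg), -1 + 1e-7), 1 - 1e-7))
        mean(zl) - mean(zr)
      },
      coherence = {
        w0 <- coh_base
        wl <- 1 - (1 - w0) / m
        nv <- 6L
        s <- a * g + b * h
        s <- (s - mean(s)) / stats::sd(s)
        vx_l <- vapply(seq_len(nv), function(j)
          wl * s + sqrt(1 - wl^2) * stats::rnorm(n_t), numeric(n_t))
        vx_r <- vapply(seq_len(nv), function(j)
          w0 * s + sqrt(1 - w0^2) * stats::rnorm(n_t), numeric(n_t))
        mean_offdiag(stats::cor(vx_l)) - mean_offdiag(stats::cor(vx_r))
      },
      stop("unknown family ", family))
  }, numeric(1))
  mean(diffs) / stats::sd(diffs)
}

mean_offdiag <- function(m) mean(m[row(m) != col(m)])

## Per-ROI multiplier vectors implied by a config's effect list.
effect_multipliers <- function(config, atlas) {
  n_roi <- nrow(atlas)
  coh_base <- if (is.null(config$coherence_base)) BASE_COHERENCE
              else config$coherence_base
  g_conn <- rep(1, n_roi)
  m_bp <- rep(1, n_roi)
  w_coh <- rep(coh_base, n_roi)
  ef <- config$effects
  if (!is.null(ef) && nrow(ef)) {
    pairs <- atlas_pairs(atlas)
    for (i in seq_len(nrow(ef))) {
      row <- pairs[pairs$pair_id == ef$pair_id[i], ]
      if (!nrow(row))
        stop("effect references pair_id ", ef$pair_id[i],
             " absent from the atlas (unpaired regions cannot carry effects)")
      roi <- if (ef$direction[i] == "left") row$roi_left else row$roi_right
      mult <- calibrate_multiplier(ef$family[i], ef$effect_size[i],
                                   config$n_timepoints, config$tr,
                                   config$noise_sd, config$band,
                                   coh_base = coh_base)
      if (ef$family[i] == "connectivity") g_conn[roi] <- mult
      if (ef$family[i] == "band_power") m_bp[roi] <- mult
      if (ef$family[i] == "coherence")
        w_coh[roi] <- 1 - (1 - coh_base) / mult
    }
  }
  list(g_conn = g_conn, m_bp = m_bp, w_coh = w_coh)
}

## Clean (noise-free) latent ROI signals for one subject; the voxel simulator
## reuses these so that ROI-level and voxel-level sessions share structure.
subject_latents <- function(config, atlas, mult, subject) {
  n_t <- config$n_timepoints
  with_seed(stream_seed(config$seed, 1L, subject), {
    g <- band_limited_series(n_t, config$tr, config$band[1], config$band[2])
    n_pairs <- config$n_pairs
    h <- vapply(seq_len(n_pairs + config$n_unpaired), function(p)
      band_limited_series(n_t, config$tr, config$band[1], config$band[2]),
      numeric(n_t))
    clean <- vapply(seq_len(nrow(atlas)), function(i) {
      p <- atlas$pair_id[i]
      latent <- if (is.na(p)) h[, n_pairs + match(atlas$roi_id[i],
                  atlas$roi_id[atlas$hemisphere == "M"])]
                else h[, p]
      mult$m_bp[i] * (BASE_GLOBAL_LOADING * mult$g_conn[i] * g +
                        BASE_PAIR_LOADING * latent)
    }, numeric(n_t))
    noise <- matrix(stats::rnorm(n_t * nrow(atlas)), n_t)
    list(clean = clean, noise = noise)
  })
}

#' Simulate a cohort of ROI BOLD timeseries
#'
#' Draws per-subject ROI timeseries from the band-limited latent-signal model,
#' together with a demographics table and a ground-truth record of the
#' implanted effects. Identical configurations (including the seed) produce
#' bit-identical output.
#'
#' @param config A [simulation_config()].
#' @param atlas Optional `atlas_table`; defaults to
#'   `make_toy_atlas(config$n_pairs, config$n_unpaired)`.
#' @return A list of class `cohort` with elements `panel` (a `bold_panel`:
#'   list of time-by-ROI matrices plus `tr`), `demographics`
#'   (data frame: `subject`, `age`, `sex`, `education`, `mmse`),
#'   `ground_truth` (effects and implanted outlier frames) and `atlas`.
#' @export
simulate_cohort <- function(config, atlas = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(atlas)) atlas <- make_toy_atlas(config$n_pairs, config$n_unpaired)
  validate_atlas(atlas)
  if (config$n_pairs != sum(atlas$hemisphere == "L"))
    stop("config atlas_spec does not match the supplied atlas")
  mult <- effect_multipliers(config, atlas)

  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    lat <- subject_latents(config, atlas, mult, s)
    y <- lat$clean + config$noise_sd * lat$noise
    colnames(y) <- atlas$name
    y
  })
  names(subjects) <- sprintf("sub-%03d", seq_len(config$n_subjects))
  panel <- bold_panel(subjects, tr = config$tr)

  demo <- with_seed(stream_seed(config$seed, 0L, 0L), {
    d <- config$demographics
    n <- config$n_subjects
    data.frame(
      subject = names(subjects),
      age = round(stats::rnorm(n, d$age_mean, d$age_sd), 1),
      sex = ifelse(stats::runif(n) < d$female_frac, "F", "M"),
      education = round(stats::rnorm(n, d$edu_mean, d$edu_sd), 1),
      mmse = pmin(30, pmax(0, round(stats::rnorm(n, d$mmse_mean, d$mmse_sd)))),
      stringsAsFactors = FALSE
    )
  })

  gt_effects <- if (is.null(config$effects)) NULL else config$effects
  gt <- list(effects = gt_effects,
             outlier_frames = config$outlier_frames)
  structure(list(panel = panel, demographics = demo, ground_truth = gt,
                 atlas = atlas, config = config),
            class = "cohort")
}

#' Simulate motion-parameter traces
#'
#' Generates smooth six-parameter head-motion traces (three translations in
#' mm, three rotations in radians) for every subject, with sharp one-frame
#' spikes implanted exactly at the configured outlier frames.
#'
#' @param config A [simulation_config()].
#' @param spike_mm Translation amplitude (mm) of each implanted spike; the
#'   default of 3 mm clearly exceeds the 0.9 mm framewise-displacement
#'   threshold.
#' @return A list of `n_subjects` matrices (`n_timepoints` x 6) with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
simulate_motion <- function(config, spike_mm = 3) {
  stopifnot(inherits(config, "sim_config"))
  n_t <- config$n_timepoints
  t_idx <- seq_len(n_t)
  lapply(seq_len(config$n_subjects), function(s) {
    with_seed(stream_seed(config$seed, 2L, s), {
      drift <- function(amp) {
        ph <- stats::runif(2, 0, 2 * pi)
        amp * (sin(2 * pi * t_idx / n_t + ph[1]) * stats::runif(1) +
                 sin(4 * pi * t_idx / n_t + ph[2]) * stats::runif(1)) +
          amp * 0.02 * stats::rnorm(n_t)
      }
      m <- cbind(tx = drift(0.15), ty = drift(0.15), tz = drift(0.15),
                 rx = drift(0.002), ry = drift(0.002), rz = drift(0.002))
      of <- config$outlier_frames
      if (!is.null(of)) {
        fr <- of$frame[of$subject == s]
        m[fr, "tx"] <- m[fr, "tx"] + spike_mm
      }
      m
    })
  })
}

#' Simulate a single-subject voxel session
#'
#' Expands one subject's latent ROI signals onto a 3-D voxel grid: all voxels
#' of a region share that region's clean latent signal with a
#' coherence-dependent mixing weight `w` (pairwise within-region correlation
#' `w^2`), background voxels are pure white noise. Voxel coordinates in mm
#' are voxel indices times `voxel_size_mm`.
#'
#' @param config A [simulation_config()]; `coherence` effects in
#'   `config$effects` raise the mixing weight on the favoured hemisphere.
#' @param atlas The cohort's `atlas_table`.
#' @param grid_shape Integer 3-vector, spatial grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param parcellation Integer array of `grid_shape` with ROI labels
#'   (0 = background); labels must be atlas `roi_id`s and every labelled
#'   region needs at least 2 voxels.
#' @param subject Subject index (1-based).
#' @return A `voxel_panel`: list with `data` (4-D array x,y,z,time),
#'   `voxel_size_mm`, `parcellation`, `tr`.
#' @export
simulate_voxel_session <- function(config, atlas, grid_shape, voxel_size_mm,
                                   parcellation, subject = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_atlas(atlas)
  parcellation <- array(as.integer(parcellation), dim = grid_shape)
  labs <- setdiff(unique(as.vector(parcellation)), 0L)
  if (!all(labs %in% atlas$roi_id))
    stop("parcellation labels not in the atlas: ",
         paste(setdiff(labs, atlas$roi_id), collapse = ", "))
  counts <- table(parcellation[parcellation > 0])
  if (any(counts < 2))
    stop("every labelled region needs at least 2 voxels ",
         "(local correlation and intrinsic connectivity are degenerate ",
         "on single-voxel regions)")
  mult <- effect_multipliers(config, atlas)
  lat <- subject_latents(config, atlas, mult, subject)
  n_t <- config$n_timepoints
  clean <- apply(lat$clean, 2, function(x) (x - mean(x)) / stats::sd(x))

  # voxel-major layout: flat is voxel x time, so array(flat, c(grid, n_t))
  # places voxel index fastest, matching the 4-D (x, y, z, time) convention
  vol <- with_seed(stream_seed(config$seed, 3L, subject), {
    flat <- matrix(stats::rnorm(prod(grid_shape) * n_t),
                   nrow = prod(grid_shape))
    lab_vec <- as.vector(parcellation)
    for (i in seq_len(nrow(atlas))) {
      idx <- which(lab_vec == atlas$roi_id[i])
      if (!length(idx)) next
      w <- mult$w_coh[i]
      if (length(idx))
        flat[idx, ] <- w * matrix(clean[, i], length(idx), n_t, byrow = TRUE) +
          sqrt(1 - w^2) * flat[idx, ]
    }
    array(flat, dim = c(grid_shape, n_t))
  })
  voxel_panel(vol, voxel_size_mm = voxel_size_mm,
              parcellation = parcellation, tr = config$tr)
}

#' Ground truth as JSON
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  jsonlite::write_json(cohort$ground_truth, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
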