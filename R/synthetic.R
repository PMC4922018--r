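# Seeded synthetic-data generators: beating-heart intensity traces and
# videos with a common-mode ventilation artifact, and jittered labeled
# kidney section stacks with optional localized blood-cell depletion.
# Every generator returns its ground truth so downstream recovery is
# testable without any recorded data.

#' Parameters of the beating-heart simulation
#'
#' Emulates the recording conditions of high-speed cardiac videography in a
#' transparent fish: a periodic cardiac intensity signal at 300 frames/s,
#' contaminated by a ventilation artifact shared by all regions of the body
#' and by sensor noise. Beat times follow a renewal process (independent
#' gamma-distributed intervals) so the true mean rate stays exactly
#' interpretable.
#'
#' @param fps frame rate, frames/second (default 300).
#' @param duration_s recording length in seconds (default 180, one
#'   steady-state window).
#' @param true_hr_bpm ground-truth mean heart rate, 30-300 bpm.
#' @param cardiac_amplitude depth of the cardiac intensity dip, intensity
#'   units (default 10).
#' @param baseline mean trace level (default 100).
#' @param ventilation_hz ventilation frequency (default 2.0 Hz).
#' @param ventilation_amplitude amplitude of the common-mode ventilation
#'   sinusoid (default half the cardiac amplitude).
#' @param noise_sd per-frame Gaussian noise SD on each trace (default 10% of
#'   the cardiac amplitude).
#' @param hr_jitter_cv beat-to-beat coefficient of variation of the
#'   interbeat interval (default 0.02).
#' @param systolic_frac fraction of the cycle spent in the fast systolic
#'   descent of the intensity pulse; the remainder is the slow diastolic
#'   recovery (default 0.3).
#' @param waveform `"pulse"` for the asymmetric raised-cosine pulse,
#'   `"cosine"` for a pure sinusoid (analytic tests).
#' @param ventilation_gain_mismatch per-trace multiplicative spread of the
#'   ventilation amplitude (0 = perfectly common-mode; used to probe
#'   imperfect cancellation).
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return an object of class `heart_sim_params`.
#' @export
heart_sim_params <- function(fps = 300, duration_s = 180, true_hr_bpm = 170,
                             cardiac_amplitude = 10, baseline = 100,
                             ventilation_hz = 2.0,
                             ventilation_amplitude = 0.5 * cardiac_amplitude,
                             noise_sd = 0.1 * cardiac_amplitude,
                             hr_jitter_cv = 0.02, systolic_frac = 0.3,
                             waveform = c("pulse", "cosine"),
                             ventilation_gain_mismatch = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  if (!is_scalar_num(fps) || fps <= 0) abort_domain("fps must be > 0")
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    abort_domain("duration_s must be > 0")
  if (!is_scalar_num(true_hr_bpm) || true_hr_bpm < 30 || true_hr_bpm > 300)
    abort_domain("true_hr_bpm must lie in [30, 300]")
  if (cardiac_amplitude <= 0) abort_domain("cardiac_amplitude must be > 0")
  if (ventilation_amplitude < 0 || noise_sd < 0 || hr_jitter_cv < 0)
    abort_domain("amplitudes, noise_sd and hr_jitter_cv must be >= 0")
  if (systolic_frac <= 0 || systolic_frac >= 1)
    abort_domain("systolic_frac must lie in (0, 1)")
  structure(
    list(fps = fps, duration_s = duration_s, true_hr_bpm = true_hr_bpm,
         cardiac_amplitude = cardiac_amplitude, baseline = baseline,
         ventilation_hz = ventilation_hz,
         ventilation_amplitude = ventilation_amplitude,
         noise_sd = noise_sd, hr_jitter_cv = hr_jitter_cv,
         systolic_frac = systolic_frac, waveform = waveform,
         ventilation_gain_mismatch = ventilation_gain_mismatch,
         seed = as.integer(seed)),
    class = "heart_sim_params")
}

# beat onset times of a gamma renewal process covering [0, duration + slack]
.gen_beat_times <- function(p) {
  mu <- 60 / p$true_hr_bpm
  n <- ceiling((p$duration_s + 4 * mu) / mu) + 8L
  intervals <- if (p$hr_jitter_cv == 0) rep(mu, n) else {
    shape <- 1 / p$hr_jitter_cv^2
    stats::rgamma(n, shape = shape, rate = shape / mu)
  }
  cumsum(c(0, intervals))
}

# asymmetric raised-cosine pulse on phase u in [0, 1): 0 at the cycle ends,
# -1 at u = systolic_frac (the end-of-diastole dip)
.cardiac_pulse <- function(u, sf) {
  ifelse(u < sf,
         -(1 - cos(pi * u / sf)) / 2,
         -(1 + cos(pi * (u - sf) / (1 - sf))) / 2)
}

#' Generate synthetic ROI intensity traces of a beating heart
#'
#' Produces the four traces the heart-rate procedure expects: three heart
#' traces carrying baseline + cardiac pulse + ventilation + independent
#' noise, and one reference trace carrying the same ventilation artifact
#' (and noise) but no cardiac component — exactly the common-mode structure
#' that reference subtraction assumes.
#'
#' @param params a [heart_sim_params()].
#' @return list with `heart_traces` (list of 3 [intensity_trace()]),
#'   `reference_trace`, and `truth`: `beat_times_s` (cycle onsets),
#'   `minima_times_s` (true dip times), `true_hr_bpm` (nominal rate),
#'   `realized_hr_bpm` (mean of per-beat rates actually generated), `seed`.
#' @export
gen_heart_trace <- function(params) {
  stopifnot(inherits(params, "heart_sim_params"))
  p <- params
  with_seed(p$seed, {
    t <- (seq_len(round(p$fps * p$duration_s)) - 1) / p$fps
    beats <- .gen_beat_times(p)
    cyc <- findInterval(t, beats)
    u <- (t - beats[cyc]) / (beats[cyc + 1L] - beats[cyc])
    cardiac <- if (p$waveform == "pulse") {
      p$cardiac_amplitude * .cardiac_pulse(u, p$systolic_frac)
    } else {
      # pure sinusoid, dip at u = systolic_frac
      -p$cardiac_amplitude / 2 *
        (1 + cos(2 * pi * (u - p$systolic_frac)))
    }
    vent <- p$ventilation_amplitude * sin(2 * pi * p$ventilation_hz * t)
    gains <- 1 + p$ventilation_gain_mismatch * stats::runif(4, -1, 1)
    heart <- lapply(1:3, function(j)
      intensity_trace(p$baseline + cardiac + gains[j] * vent +
                        stats::rnorm(length(t), 0, p$noise_sd), p$fps))
    ref <- intensity_trace(p$baseline + gains[4] * vent +
                             stats::rnorm(length(t), 0, p$noise_sd), p$fps)
    ivals <- diff(beats)
    in_rec <- beats[-length(beats)] < p$duration_s
    minima_t <- beats[-length(beats)] + p$systolic_frac * ivals
    list(heart_traces = heart, reference_trace = ref,
         truth = list(beat_times_s = beats[-length(beats)][in_rec],
                      minima_times_s = minima_t[minima_t < p$duration_s],
                      true_hr_bpm = p$true_hr_bpm,
                      realized_hr_bpm = mean(60 / ivals[in_rec]),
                      seed = p$seed))
  })
}

#' Render a synthetic beating-heart video
#'
#' Spatial rendering of the trace model: pixels inside the heart region
#' carry the cardiac + ventilation signal, all other body pixels carry the
#' ventilation signal only, and every pixel receives independent Gaussian
#' noise. ROI means over the generated stack therefore reproduce the trace
#' model up to noise averaging.
#'
#' @param params a [heart_sim_params()].
#' @param frame_shape `c(H, W)` in pixels (default 384 x 512, the recording
#'   resolution emulated; tests use smaller frames).
#' @param heart_region a [roi()] delimiting the heart; default a central
#'   rectangle of one quarter the frame in each dimension.
#' @param rois optional [roi_set()]; by default three rectangles are tiled
#'   inside the heart region and the reference is placed outside it.
#' @return list with `stack` (a [frame_stack()]), `rois` (a [roi_set()]),
#'   and `truth` as in [gen_heart_trace()].
#' @export
gen_heart_video <- function(params, frame_shape = c(384L, 512L),
                            heart_region = NULL, rois = NULL) {
  stopifnot(inherits(params, "heart_sim_params"))
  H <- frame_shape[1]; W <- frame_shape[2]
  if (is.null(heart_region))
    heart_region <- roi(round(H * 3 / 8), round(W * 3 / 8),
                        round(H * 5 / 8), round(W * 5 / 8))
  if (heart_region$row1 > H || heart_region$col1 > W)
    abort_domain("heart_region exceeds the frame")
  if (is.null(rois)) rois <- .default_rois(heart_region, H, W)
  for (r in rois$heart_rois)
    if (r$row0 < heart_region$row0 || r$row1 > heart_region$row1 ||
        r$col0 < heart_region$col0 || r$col1 > heart_region$col1)
      abort_domain("heart ROIs must lie inside the heart region")
  if (.roi_overlaps(rois$reference_roi, heart_region))
    abort_domain("reference ROI must lie outside the heart region")

  p <- params
  tr <- gen_heart_trace(p)  # consumes p$seed deterministically
  Tn <- length(tr$heart_traces[[1]]$values)
  t <- (seq_len(Tn) - 1) / p$fps
  vent <- p$ventilation_amplitude * sin(2 * pi * p$ventilation_hz * t)
  # recover the noiseless cardiac component from the generated traces:
  # regenerate it with the same seed-derived beat times via truth
  cardiac <- with_seed(p$seed, {
    beats <- .gen_beat_times(p)
    cyc <- findInterval(t, beats)
    u <- (t - beats[cyc]) / (beats[cyc + 1L] - beats[cyc])
    if (p$waveform == "pulse")
      p$cardiac_amplitude * .cardiac_pulse(u, p$systolic_frac)
    else -p$cardiac_amplitude / 2 * (1 + cos(2 * pi * (u - p$systolic_frac)))
  })
  frames <- with_seed(p$seed + 7L, {
    noise <- if (p$noise_sd > 0)
      array(stats::rnorm(H * W * Tn, 0, p$noise_sd), c(H, W, Tn))
    else array(0, c(H, W, Tn))
    base <- array(rep(p$baseline + vent, each = H * W), c(H, W, Tn))
    hr_rows <- (heart_region$row0 + 1L):heart_region$row1
    hr_cols <- (heart_region$col0 + 1L):heart_region$col1
    add <- array(rep(cardiac, each = length(hr_rows) * length(hr_cols)),
                 c(length(hr_rows), length(hr_cols), Tn))
    base[hr_rows, hr_cols, ] <- base[hr_rows, hr_cols, ] + add
    pmax(base + noise, 0)
  })
  list(stack = frame_stack(frames, p$fps), rois = rois, truth = tr$truth)
}

.default_rois <- function(heart_region, H, W) {
  hr <- heart_region
  h3 <- (hr$row1 - hr$row0) %/% 3
  heart_rois <- lapply(0:2, function(k)
    roi(hr$row0 + k * h3, hr$col0, hr$row0 + (k + 1) * h3, hr$col1))
  # reference above the heart region (or below if no room)
  ref_h <- max(2L, h3)
  ref <- if (hr$row0 >= ref_h)
    roi(hr$row0 - ref_h, hr$col0, hr$row0, hr$col1)
  else roi(hr$row1, hr$col0, min(H, hr$row1 + ref_h), hr$col1)
  roi_set(heart_rois, ref)
}

#' Parameters of the synthetic serial-section kidney
#'
#' Emulates 5-um-thick serial-section stacks of an ellipsoidal
#' haematopoietic kidney: each voxel of the organ is labeled blood-cell by
#' an independent Bernoulli draw whose probability varies in space
#' (optionally depleted inside a dorsal band or over the whole organ), and
#' each section is translated by integer-rounded Gaussian jitter to emulate
#' mounting misalignment.
#'
#' @param semi_axes_um ellipsoid semi-axes `c(row, col, z)` in um.
#' @param center_um ellipsoid centre `c(row, col, z)` in um; defaults to the
#'   grid centre.
#' @param grid_shape `c(H, W)` section size in pixels.
#' @param pixel_size_um in-plane pixel size (default 10).
#' @param n_sections number of sections.
#' @param thickness_um section thickness (default 5).
#' @param blood_fraction baseline Bernoulli probability of the blood-cell
#'   label inside the organ (default 0.25).
#' @param depletion one of `"none"`, `"dorsal_band"`, `"whole"`.
#' @param depletion_depth_um for `"dorsal_band"`: band extent, measured from
#'   the dorsal (row 0) surface of the grid, in um.
#' @param depletion_factor fractional reduction of the blood probability
#'   inside the depleted region, in `[0, 1]` (1 = complete loss).
#' @param jitter_sd_px SD of the per-section Gaussian jitter in pixels
#'   (rounded to integers when applied).
#' @param margin_px required clearance between the organ and the grid
#'   border, in pixels; must be at least the largest expected jitter.
#' @param seed integer RNG seed.
#' @return an object of class `section_sim_params`.
#' @export
section_sim_params <- function(semi_axes_um = c(250, 350, 150),
                               center_um = NULL,
                               grid_shape = c(100L, 120L),
                               pixel_size_um = 10, n_sections = 70L,
                               thickness_um = 5, blood_fraction = 0.25,
                               depletion = c("none", "dorsal_band", "whole"),
                               depletion_depth_um = 0,
                               depletion_factor = 1,
                               jitter_sd_px = 0, margin_px = 10,
                               seed = 1L) {
  depletion <- match.arg(depletion)
  if (length(semi_axes_um) != 3L || any(semi_axes_um <= 0))
    abort_domain("semi_axes_um must be 3 positive values")
  if (is.null(center_um))
    center_um <- c(grid_shape[1] / 2 * pixel_size_um,
                   grid_shape[2] / 2 * pixel_size_um,
                   n_sections / 2 * thickness_um)
  if (blood_fraction < 0 || blood_fraction > 1 ||
      depletion_factor < 0 || depletion_factor > 1)
    abort_domain("fractions must lie in [0, 1]")
  if (jitter_sd_px < 0 || margin_px < 0)
    abort_domain("jitter_sd_px and margin_px must be >= 0")
  # organ must fit the grid with the stated margin
  lo_px <- (center_um[1:2] - semi_axes_um[1:2]) / pixel_size_um
  hi_px <- (center_um[1:2] + semi_axes_um[1:2]) / pixel_size_um
  if (any(lo_px < margin_px) ||
      hi_px[1] > grid_shape[1] - margin_px ||
      hi_px[2] > grid_shape[2] - margin_px)
    abort_domain("organ does not fit in the grid with margin_px clearance")
  structure(
    list(semi_axes_um = semi_axes_um, center_um = center_um,
         grid_shape = as.integer(grid_shape),
         pixel_size_um = pixel_size_um,
         n_sections = as.integer(n_sections), thickness_um = thickness_um,
         blood_fraction = blood_fraction, depletion = depletion,
         depletion_depth_um = depletion_depth_um,
         depletion_factor = depletion_factor,
         jitter_sd_px = jitter_sd_px, margin_px = margin_px,
         seed = as.integer(seed)),
    class = "section_sim_params")
}

#' Generate a jittered labeled kidney section stack with ground truth
#'
#' @param params a [section_sim_params()].
#' @return list with `stack` (the jittered [section_stack()]), and `truth`:
#'   `unjittered` (the aligned stack), `shifts_px` (`S x 2` applied
#'   integer shifts), `shifts_raw_px` (the unrounded Gaussian draws),
#'   `analytic_volume_um3` (4/3 pi abc), `voxel_volume_um3` (voxelized,
#'   pre-jitter), `per_section_blood_p` (expected per-section blood
#'   probability), `seed`.
#' @export
gen_section_stack <- function(params) {
  stopifnot(inherits(params, "section_sim_params"))
  p <- params
  with_seed(p$seed, {
    H <- p$grid_shape[1]; W <- p$grid_shape[2]; S <- p$n_sections
    row_um <- (seq_len(H) - 0.5) * p$pixel_size_um
    col_um <- (seq_len(W) - 0.5) * p$pixel_size_um
    z_um <- (seq_len(S) - 0.5) * p$thickness_um
    labels <- array(0L, c(H, W, S))
    rr <- matrix(row_um, H, W)
    cc <- matrix(col_um, H, W, byrow = TRUE)
    p_expected <- numeric(S)
    depleted_px <- if (p$depletion == "dorsal_band")
      rr <= p$depletion_depth_um else NULL
    for (s in seq_len(S)) {
      rad2 <- 1 - ((z_um[s] - p$center_um[3]) / p$semi_axes_um[3])^2
      if (rad2 <= 0) { p_expected[s] <- NA_real_; next }
      inside <- ((rr - p$center_um[1]) / p$semi_axes_um[1])^2 +
        ((cc - p$center_um[2]) / p$semi_axes_um[2])^2 <= rad2
      if (!any(inside)) { p_expected[s] <- NA_real_; next }
      prob <- matrix(p$blood_fraction, H, W)
      if (p$depletion == "whole") {
        prob[] <- p$blood_fraction * (1 - p$depletion_factor)
      } else if (p$depletion == "dorsal_band") {
        prob[depleted_px] <- p$blood_fraction * (1 - p$depletion_factor)
      }
      sec <- matrix(0L, H, W)
      sec[inside] <- 1L
      draws <- stats::runif(sum(inside)) < prob[inside]
      sec[inside][draws] <- 2L
      labels[, , s] <- sec
      p_expected[s] <- mean(prob[inside])
    }
    shifts_raw <- matrix(stats::rnorm(2 * S, 0, p$jitter_sd_px), S, 2)
    if (p$jitter_sd_px == 0) shifts_raw[] <- 0
    shifts <- round(shifts_raw)
    jittered <- labels
    for (s in seq_len(S)) {
      if (shifts[s, 1] != 0 || shifts[s, 2] != 0)
        jittered[, , s] <- .translate_int(labels[, , s],
                                          shifts[s, 1], shifts[s, 2])
    }
    colnames(shifts) <- colnames(shifts_raw) <- c("d_row", "d_col")
    list(stack = section_stack(jittered, p$pixel_size_um, p$thickness_um),
         truth = list(
           unjittered = section_stack(labels, p$pixel_size_um,
                                      p$thickness_um),
           shifts_px = shifts, shifts_raw_px = shifts_raw,
           analytic_volume_um3 = 4 / 3 * pi * prod(p$semi_axes_um),
           voxel_volume_um3 = sum(labels > 0L) * p$pixel_size_um^2 *
             p$thickness_um,
           per_section_blood_p = p_expected,
           seed = p$seed))
  })
}
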