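# Shared fixtures, built in code at test time.

# cosine trace with period (frames) and given length; minima at
# period/2, 3*period/2, ... (0-based), i.e. 1-based index period/2 + 1, ...
cosine_trace <- function(n = 1000, period = 100, fps = 300, amplitude = 1,
                         noise_sd = 0, seed = NULL) {
  t <- seq_len(n) - 1
  x <- amplitude * cos(2 * pi * t / period)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  intensity_trace(x, fps)
}

# tiny frame stack with a constant value per frame
constant_stack <- function(values, H = 8, W = 10, fps = 300) {
  frames <- array(rep(values, each = H * W), c(H, W, length(values)))
  frame_stack(frames, fps)
}

# small 3-group fixture with a known strong effect in the last group
shifted_groups <- function(n = 10, shift = 10, seed = 1) {
  set.seed(seed)
  sds <- 1
  list(a = rnorm(n, 0, sds), b = rnorm(n, 0, sds),
       c = rnorm(n, shift, sds))
}

# heart-rate group summaries as printed for days 5 and 7 after irradiation
hr_day5_summary <- function() {
  data.frame(label = c("control", "DR", "VR"), n = c(3, 5, 4),
             mean = c(165, 174, 169), sd = c(5.35, 12.9, 8.14))
}
hr_day7_summary <- function() {
  data.frame(label = c("control", "DR", "VR"), n = c(6, 6, 4),
             mean = c(171, 172, 170), sd = c(7.78, 6.99, 6.47))
}
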