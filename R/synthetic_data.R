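# Synthetic frame-level corpora with known coupling between windowed
# sinusoidal pitch excursions and Gaussian-bump brow raises. Used for
# end-to-end parameter-recovery testing; not an acoustic F0 synthesizer.

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the structure of a five-speaker TV-interview sample:
#' segment lengths around 68 frames (2.28 s at 30 fps, SD 1.08 s),
#' Gaussian-bump brow raises with SD 6 frames (so the significantly
#' elevated region spans roughly +/-9 frames), windowed sinusoidal pitch
#' excursions over the 19-frame pre-peak and 17-frame post-peak regions,
#' and voiceless gaps. Brow-peak height is linearly coupled to the sinusoid
#' parameters with per-speaker random intercepts; the default coupling
#' coefficients mirror the effect sizes of the combined-region model of the
#' analysis (intercept 0.213, post amplitude 0.162, post frequency 0.387,
#' pre phase 0.238, all others 0).
#'
#' @param n_speakers Number of speakers (default 5).
#' @param segments_per_speaker Segments per speaker (default 150).
#' @param fps Frames per second (fixed convention 30).
#' @param segment_length_mean,segment_length_sd Normal sampler for segment
#'   lengths in frames (defaults 68 and 32, clamped to `[40, 200]`).
#' @param bump_sd Brow-bump standard deviation in frames (default 6).
#' @param coupling Named coefficients of the peak-height model: `intercept`
#'   plus any of `I_pre`, `A_pre`, `f_pre`, `phi_pre`, `I_post`, `A_post`,
#'   `f_post`, `phi_post`.
#' @param speaker_intercept_sd SD of speaker random intercepts (default
#'   0.3).
#' @param residual_sd Residual SD of peak heights (default 0.6).
#' @param A_range,f_range,phi_range,I_range Uniform sampling ranges of the
#'   sinusoid parameters (amplitude z-units, frequency cycles/s, phase pi
#'   units, baseline z-units).
#' @param pre_size,post_size Coupled window sizes in frames (defaults 19,
#'   17).
#' @param missing_rate Long-run fraction of voiceless (missing-pitch)
#'   frames (default 0.05); voiceless runs start at rate
#'   `missing_rate / missing_run_mean` per voiced frame.
#' @param missing_run_mean Mean voiceless run length in frames (default 4).
#' @param ar_rho,ar_sd AR(1) coefficient and innovation SD of the eyebrow
#'   measurement noise (defaults 0.5, 0.1).
#' @param walk_sd Step SD of the bounded random walk generating pitch
#'   outside the coupled windows (default 0.1).
#' @param seed Integer seed (required); all randomness flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_speakers = 5L,
                             segments_per_speaker = 150L,
                             fps = 30,
                             segment_length_mean = 68,
                             segment_length_sd = 32,
                             bump_sd = 6,
                             coupling = c(intercept = 0.213,
                                          A_post = 0.162,
                                          f_post = 0.387,
                                          phi_pre = 0.238),
                             speaker_intercept_sd = 0.3,
                             residual_sd = 0.6,
                             A_range = c(0.2, 3),
                             f_range = c(0.2, 1.2),
                             phi_range = c(0, 2),
                             I_range = c(-1, 1),
                             pre_size = 19L,
                             post_size = 17L,
                             missing_rate = 0.05,
                             missing_run_mean = 4,
                             ar_rho = 0.5,
                             ar_sd = 0.1,
                             walk_sd = 0.1,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  full <- c(intercept = 0, I_pre = 0, A_pre = 0, f_pre = 0, phi_pre = 0,
            I_post = 0, A_post = 0, f_post = 0, phi_post = 0)
  if (length(coupling)) {
    bad <- setdiff(names(coupling), names(full))
    if (length(bad)) stop("unknown coupling term(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(coupling)] <- coupling
  }
  ranges <- list(A_range = A_range, f_range = f_range,
                 phi_range = phi_range, I_range = I_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[2L] < r[1L]) {
      stop("invalid ", nm, ": must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  stopifnot(n_speakers >= 1, segments_per_speaker >= 1, fps > 0,
            bump_sd > 0, speaker_intercept_sd >= 0, residual_sd >= 0,
            missing_rate >= 0, missing_rate <= 1, missing_run_mean >= 1,
            ar_sd >= 0, walk_sd >= 0, pre_size >= 5, post_size >= 5)
  structure(list(
    n_speakers = as.integer(n_speakers),
    segments_per_speaker = as.integer(segments_per_speaker),
    fps = fps, segment_length_mean = segment_length_mean,
    segment_length_sd = segment_length_sd, bump_sd = bump_sd,
    coupling = full, speaker_intercept_sd = speaker_intercept_sd,
    residual_sd = residual_sd, A_range = A_range, f_range = f_range,
    phi_range = phi_range, I_range = I_range,
    pre_size = as.integer(pre_size), post_size = as.integer(post_size),
    missing_rate = missing_rate, missing_run_mean = missing_run_mean,
    ar_rho = ar_rho, ar_sd = ar_sd, walk_sd = walk_sd,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Gaussian-bump brow trajectory with AR(1) measurement noise
#'
#' The noiseless component is `h * exp(-(p - peak_pos)^2 / (2 * bump_sd^2))`
#' over frame offsets `p = 0 ... length - 1`, so it is maximal (value `h`)
#' at `peak_pos` with half-width at half-maximum about `1.177 * bump_sd`
#' frames. AR(1) noise with coefficient `ar_rho` and innovation SD `ar_sd`
#' is added. Uses the current RNG state.
#'
#' @param h Peak height (z-units).
#' @param bump_sd Bump SD in frames.
#' @param length Series length in frames.
#' @param peak_pos 0-based peak offset, `0 <= peak_pos < length`.
#' @param ar_rho,ar_sd AR(1) noise spec; `ar_sd = 0` disables noise.
#' @return Numeric vector of length `length`.
#' @export
generate_brow_trajectory <- function(h, bump_sd, length, peak_pos,
                                     ar_rho = 0.5, ar_sd = 0.1) {
  stopifnot(peak_pos >= 0, peak_pos < length)
  p <- seq_len(length) - 1L
  base <- h * exp(-(p - peak_pos)^2 / (2 * bump_sd^2))
  if (ar_sd > 0) {
    noise <- as.numeric(stats::filter(stats::rnorm(length, 0, ar_sd),
                                      ar_rho, method = "recursive"))
    base <- base + noise
  }
  base
}

# Smooth bounded random walk: correlated increments (momentum rho) so the
# series has a continuous-looking derivative, seeded with slope0 to leave
# the coupled sine window tangentially.
.bounded_walk <- function(start, n, sd, slope0 = 0, bound = 3, rho = 0.7) {
  if (n <= 0L) return(numeric(0L))
  out <- numeric(n)
  x <- start
  step <- slope0
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  for (i in seq_len(n)) {
    step <- rho * step + innov[i]
    x <- x + step
    if (x > bound) { x <- 2 * bound - x; step <- -step }
    if (x < -bound) { x <- -2 * bound - x; step <- -step }
    out[i] <- x
  }
  out
}

# per-frame slope of the sinusoid at time t (seconds)
.sine_slope <- function(p, t, fps) {
  p$A * 2 * pi * p$f * cos(2 * pi * p$f * t + p$phi * pi) / fps
}

# `rate` is the long-run voiceless fraction; runs of geometric mean length
# `run_mean` therefore start at rate/run_mean per voiced frame.
.mask_voiceless <- function(x, rate, run_mean) {
  if (rate <= 0) return(x)
  start_p <- rate / run_mean
  n <- length(x)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1L) < start_p) {
      len <- stats::rgeom(1L, 1 / run_mean) + 1L
      x[i:min(n, i + len - 1L)] <- NA_real_
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  x
}

# Pitch values for segment-relative positions around the peak.
# Pre sine covers rel positions -(pre_size-1)..0 with t = 0 at the region
# start; the post baseline is derived from continuity at the peak so both
# regions share the peak value exactly (keeps the pre and post parameter
# sets simultaneously recoverable).
.window_pitch <- function(rel, pre, post, pre_size, post_size, fps) {
  t_peak <- (pre_size - 1) / fps
  peak_val <- sine_value(t_peak, pre$I, pre$A, pre$f, pre$phi)
  post$I <- peak_val - post$A * sin(post$phi * pi)
  val <- rep(NA_real_, length(rel))
  in_pre <- rel >= -(pre_size - 1) & rel <= 0
  in_post <- rel > 0 & rel <= post_size - 1
  val[in_pre] <- sine_value((rel[in_pre] + pre_size - 1) / fps,
                            pre$I, pre$A, pre$f, pre$phi)
  val[in_post] <- sine_value(rel[in_post] / fps,
                             post$I, post$A, post$f, post$phi)
  list(values = val, post = post)
}

#' Synthetic 121-position pitch window
#'
#' Builds the pitch series of one analysis window: the pre-region sine over
#' positions `-(pre_size - 1) ... 0`, the post-region sine over
#' `1 ... post_size - 1` (its baseline re-derived so both sines share the
#' peak value), a bounded random walk elsewhere, and optional voiceless
#' masking. With masking off, [fit_region()] recovers both parameter sets.
#'
#' @param pre,post Named lists with `I`, `A`, `f`, `phi`. The post `I` is
#'   overridden by the continuity constraint; the returned `post` carries
#'   the value actually used.
#' @param pre_size,post_size Region sizes in frames (defaults 19, 17).
#' @param fps Frames per second.
#' @param missing_rate,missing_run_mean Voiceless masking spec (rate 0
#'   disables).
#' @param walk_sd Step SD of the out-of-window random walk.
#' @return A list with `values` (length-121 vector, positions -60..60),
#'   `positions`, `pre`, and the adjusted `post`.
#' @export
generate_pitch_window <- function(pre, post, pre_size = 19L, post_size = 17L,
                                  fps = 30, missing_rate = 0,
                                  missing_run_mean = 4, walk_sd = 0.1) {
  positions <- -60:60
  w <- .window_pitch(positions, pre, post, pre_size, post_size, fps)
  val <- w$values
  left <- positions < -(pre_size - 1)
  right <- positions > post_size - 1
  lw <- .bounded_walk(val[positions == -(pre_size - 1)], sum(left), walk_sd,
                      slope0 = -.sine_slope(pre, 0, fps))
  val[left] <- rev(lw)
  val[right] <- .bounded_walk(val[positions == post_size - 1], sum(right),
                              walk_sd,
                              slope0 = .sine_slope(w$post,
                                                   (post_size - 1) / fps,
                                                   fps))
  val <- .mask_voiceless(val, missing_rate, missing_run_mean)
  list(values = val, positions = positions, pre = pre, post = w$post)
}

.runif_range <- function(r) stats::runif(1L, r[1L], r[2L])

#' Generate a synthetic frame-level corpus with ground truth
#'
#' For each segment: pre- and post-region sinusoid parameters are drawn
#' uniformly from the configured ranges (the post baseline derived by
#' continuity at the peak); the brow-peak height is
#' `intercept + sum(coupling * params) + speaker intercept +
#' N(0, residual_sd)`; the eyebrow series is a Gaussian bump of that height
#' with AR(1) noise; pitch follows the two sines inside the coupled windows,
#' a bounded random walk elsewhere, with voiceless runs masked. Output is
#' deterministic given the config (which includes the seed).
#'
#' @param config A [synthetic_config()].
#' @return A list with `frames` (frame table), `segments` (segment table),
#'   and `truth` (list: `segments` data.frame of generative parameters and
#'   peak heights, `speakers` data.frame of random intercepts, `coupling`
#'   vector, `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cg <- config
  speakers <- sprintf("S%02d", seq_len(cg$n_speakers))
  episodes <- sprintf("%04d", seq_len(cg$n_speakers))
  sp_int <- stats::rnorm(cg$n_speakers, 0, cg$speaker_intercept_sd)
  min_len <- cg$pre_size + cg$post_size + 4L

  frame_list <- list()
  seg_list <- list()
  truth_list <- list()
  for (s in seq_len(cg$n_speakers)) {
    cursor <- 0L
    for (j in seq_len(cg$segments_per_speaker)) {
      len <- round(stats::rnorm(1L, cg$segment_length_mean,
                                cg$segment_length_sd))
      len <- as.integer(min(200L, max(min_len, len)))
      seg_id <- sprintf("%s-%04d", episodes[s], j)
      pre <- list(I = .runif_range(cg$I_range), A = .runif_range(cg$A_range),
                  f = .runif_range(cg$f_range),
                  phi = .runif_range(cg$phi_range))
      post0 <- list(I = .runif_range(cg$I_range),
                    A = .runif_range(cg$A_range),
                    f = .runif_range(cg$f_range),
                    phi = .runif_range(cg$phi_range))
      peak_pos <- if (len - cg$post_size >= cg$pre_size - 1L) {
        sample(seq.int(cg$pre_size - 1L, len - cg$post_size), 1L)
      } else cg$pre_size - 1L
      post <- post0
      b <- cg$coupling
      h <- b[["intercept"]] +
        b[["I_pre"]] * pre$I + b[["A_pre"]] * pre$A +
        b[["f_pre"]] * pre$f + b[["phi_pre"]] * pre$phi +
        b[["I_post"]] * post$I + b[["A_post"]] * post$A +
        b[["f_post"]] * post$f + b[["phi_post"]] * post$phi +
        sp_int[s] + stats::rnorm(1L, 0, cg$residual_sd)
      eyebrow <- generate_brow_trajectory(h, cg$bump_sd, len, peak_pos,
                                          cg$ar_rho, cg$ar_sd)
      # anchor the coupled pitch windows at the realized eyebrow maximum
      # (the apex the analysis will center its windows on), not at the
      # noiseless bump center
      anchor <- which.max(eyebrow) - 1L
      rel <- seq_len(len) - 1L - anchor
      w <- .window_pitch(rel, pre, post0, cg$pre_size, cg$post_size, cg$fps)
      post <- w$post
      pitch <- w$values
      left_n <- sum(rel < -(cg$pre_size - 1L))
      right_n <- sum(rel > cg$post_size - 1L)
      if (left_n > 0L) {
        pitch[seq_len(left_n)] <-
          rev(.bounded_walk(pitch[left_n + 1L], left_n, cg$walk_sd,
                            slope0 = -.sine_slope(pre, 0, cg$fps)))
      }
      if (right_n > 0L) {
        pitch[(len - right_n + 1L):len] <-
          .bounded_walk(pitch[len - right_n], right_n, cg$walk_sd,
                        slope0 = .sine_slope(post,
                                             (cg$post_size - 1) / cg$fps,
                                             cg$fps))
      }
      pitch <- .mask_voiceless(pitch, cg$missing_rate, cg$missing_run_mean)
      frames <- seq.int(cursor, cursor + len - 1L)
      frame_list[[length(frame_list) + 1L]] <- data.frame(
        speaker = speakers[s], episode = episodes[s], segment_id = seg_id,
        frame = frames, eyebrow_height = eyebrow,
        lat_angle = stats::rnorm(len, 0, 2),
        sag_angle = stats::rnorm(len, 0, 2),
        pitch = pitch, stringsAsFactors = FALSE)
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        segment_id = seg_id, episode = episodes[s],
        start_frame = cursor, end_frame = cursor + len,
        text = "", stringsAsFactors = FALSE)
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        segment_id = seg_id, speaker = speakers[s],
        I_pre = pre$I, A_pre = pre$A, f_pre = pre$f, phi_pre = pre$phi,
        I_post = post$I, A_post = post$A, f_post = post$f,
        phi_post = post$phi,
        peak_height = h, peak_frame = cursor + anchor,
        bump_center = cursor + peak_pos,
        segment_length = len, stringsAsFactors = FALSE)
      cursor <- cursor + len
    }
  }
  frames <- do.call(rbind, frame_list)
  segments <- do.call(rbind, seg_list)
  truth_seg <- do.call(rbind, truth_list)
  rownames(frames) <- rownames(segments) <- rownames(truth_seg) <- NULL
  list(frames = frames, segments = segments,
       truth = list(segments = truth_seg,
                    speakers = data.frame(speaker = speakers,
                                          intercept = sp_int,
                                          stringsAsFactors = FALSE),
                    coupling = cg$coupling,
                    config = cg))
}
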