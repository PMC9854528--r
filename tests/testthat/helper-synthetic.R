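# Shared fixtures: rotation matrices, hand-built windows, truth-level fit
# tables. Everything is generated in code; no stored data.

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# a segment_window built directly from pitch/eyebrow vectors
make_window <- function(pitch, eyebrow = NULL, segment_id = "0001-0001",
                        speaker = "S01", peak_height = 1) {
  stopifnot(length(pitch) == 121L)
  if (is.null(eyebrow)) eyebrow <- rep(0, 121L)
  structure(list(segment_id = segment_id, speaker = speaker,
                 peak_frame = 60L, peak_height = peak_height,
                 positions = -60:60, eyebrow = eyebrow, pitch = pitch),
            class = "segment_window")
}

# windows of pure N(0,1) noise for null-distribution tests
noise_windows <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    make_window(pitch = rnorm(121), eyebrow = rnorm(121),
                segment_id = sprintf("0001-%04d", i),
                peak_height = rnorm(1)))
}

# fit-table-shaped data straight from generator truth (planted parameters)
truth_fit_tables <- function(d) {
  tr <- d$truth$segments
  mk <- function(reg) data.frame(
    segment_id = tr$segment_id, speaker = tr$speaker,
    I = tr[[paste0("I_", reg)]], A = tr[[paste0("A_", reg)]],
    f = tr[[paste0("f_", reg)]], phi = tr[[paste0("phi_", reg)]],
    skipped = FALSE, converged = TRUE, stringsAsFactors = FALSE)
  list(pre = mk("pre"), post = mk("post"),
       peaks = data.frame(segment_id = tr$segment_id, speaker = tr$speaker,
                          peak_height = tr$peak_height,
                          stringsAsFactors = FALSE))
}

peaks_from_windows <- function(windows) {
  data.frame(
    segment_id = vapply(windows, `[[`, character(1L), "segment_id"),
    speaker = vapply(windows, `[[`, character(1L), "speaker"),
    peak_height = vapply(windows, `[[`, numeric(1L), "peak_height"),
    stringsAsFactors = FALSE)
}

# default coupling truth in combined-model term order
combined_truth <- c("(Intercept)" = 0.213, A_pre = 0, f_pre = 0,
                    phi_pre = 0.238, A_post = 0.162, f_post = 0.387)

# folded distance between two phases in [0, 2)
phi_dist <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 2 - d)
}
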