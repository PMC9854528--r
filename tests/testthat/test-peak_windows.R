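frames_df <- function(frames, eyebrow, pitch = NA_real_, speaker = "S01",
                      episode = "0001", segment_id = NA_character_) {
  data.frame(speaker = speaker, episode = episode, segment_id = segment_id,
             frame = frames, eyebrow_height = eyebrow, lat_angle = 0,
             sag_angle = 0, pitch = pitch, stringsAsFactors = FALSE)
}

seg_df <- function(ids, starts, ends, episode = "0001") {
  data.frame(segment_id = ids, episode = episode, start_frame = starts,
             end_frame = ends, text = "", stringsAsFactors = FALSE)
}

test_that("attach_segments uses half-open intervals and flags overlap", {
  recs <- frames_df(0:99, eyebrow = rnorm(100))
  segs <- seg_df(c("0001-0001", "0001-0002", "0001-0003"),
                 c(10L, 30L, 60L), c(30L, 60L, 80L))
  out <- attach_segments(recs, segs)
  expect_identical(out$segment_id[out$frame == 45L], "0001-0002")
  expect_identical(out$segment_id[out$frame == 60L], "0001-0003")  # half-open
  expect_true(is.na(out$segment_id[out$frame == 5L]))
  counts <- table(out$segment_id)
  expect_equal(unname(as.integer(counts)),
               as.integer(segs$end_frame - segs$start_frame))

  bad <- seg_df(c("0001-0001", "0001-0002"), c(10L, 25L), c(30L, 40L))
  expect_error(attach_segments(recs, bad), "0001-0001.*0001-0002")
})

test_that("find_eyebrow_peak returns the earliest maximal frame", {
  recs <- frames_df(0:9, eyebrow = seq(0, 0.9, by = 0.1))
  expect_identical(find_eyebrow_peak(recs)$peak_frame, 9L)

  eb <- c(0, 1, 0.5, 1, 0)
  recs <- frames_df(10:14, eyebrow = eb)
  expect_identical(find_eyebrow_peak(recs)$peak_frame, 11L)
  # order of rows does not matter
  expect_identical(find_eyebrow_peak(recs[c(3, 1, 5, 2, 4), ])$peak_frame, 11L)

  set.seed(42)
  eb <- 2 * exp(-((0:99) - 40)^2 / 50) + rnorm(100, 0, 0.01)
  recs <- frames_df(0:99, eyebrow = eb)
  expect_lte(abs(find_eyebrow_peak(recs)$peak_frame - 40L), 1L)

  expect_error(find_eyebrow_peak(frames_df(0:2, eyebrow = NA_real_)),
               "no non-missing")
})

test_that("extract_window truncates to the segment and is shift-invariant", {
  set.seed(1)
  eb <- rnorm(80); pi_ <- rnorm(80)
  recs <- frames_df(100:179, eyebrow = eb, pitch = pi_,
                    segment_id = "0001-0001")
  # peak 10 frames after the segment start: positions -60..-11 missing
  w <- extract_window(recs, peak_frame = 110L)
  expect_true(all(is.na(w$pitch[w$positions < -10])))
  expect_false(anyNA(w$pitch[w$positions >= -10 & w$positions <= 69 - 10]))
  expect_identical(w$eyebrow[w$positions == 0], eb[11L])

  # a 121-frame segment with the peak at its center has no structural gaps
  recs2 <- frames_df(0:120, eyebrow = rnorm(121), pitch = rnorm(121),
                     segment_id = "0001-0002")
  w2 <- extract_window(recs2, peak_frame = 60L)
  expect_false(anyNA(w2$pitch))

  shifted <- recs
  shifted$frame <- shifted$frame + 7L
  w3 <- extract_window(shifted, peak_frame = 117L)
  expect_equal(w3$pitch, w$pitch)
  expect_equal(w3$eyebrow, w$eyebrow)

  expect_error(extract_window(recs, peak_frame = 500L), "not inside")
})

test_that("windows built from a frame stream put the maximum at position 0", {
  d <- generate_dataset(synthetic_config(n_speakers = 2L,
                                         segments_per_speaker = 10L,
                                         seed = 9))
  windows <- build_windows(d$frames)
  expect_length(windows, 20L)
  for (w in windows) {
    expect_equal(w$eyebrow[w$positions == 0], max(w$eyebrow, na.rm = TRUE))
  }
})

test_that("interpolate_missing bridges interior gaps and extends edges", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(NA, 5, NA)), c(5, 5, 5))

  # exact on affine signals regardless of which 20% is masked
  set.seed(8)
  y <- 2 * (1:50)
  for (rep in 1:5) {
    ym <- y
    idx <- sample(2:49, 10L)
    ym[idx] <- NA
    expect_equal(interpolate_missing(ym), y, tolerance = 1e-12)
  }
  # observed values are never altered
  y2 <- c(4, NA, -1, 7, NA, NA, 0)
  out <- interpolate_missing(y2)
  expect_identical(out[!is.na(y2)], y2[!is.na(y2)])
  expect_error(interpolate_missing(c(NA_real_, NA_real_)), "at least 1")
})

test_that("raise_scope is rank-based and detects elevated positions", {
  wins <- noise_windows(40L, seed = 21)
  sc <- raise_scope(wins)
  shifted <- lapply(wins, function(w) { w$eyebrow <- w$eyebrow + 5; w })
  sc2 <- raise_scope(shifted)
  expect_equal(sc$p_values, sc2$p_values, tolerance = 1e-12)
  # any monotone transform leaves the ranks alone
  mono <- lapply(wins, function(w) { w$eyebrow <- exp(w$eyebrow); w })
  sc3 <- raise_scope(mono)
  expect_equal(sc$p_values, sc3$p_values, tolerance = 1e-12)

  # a planted bump is detected around the peak
  set.seed(33)
  bump <- lapply(1:150, function(i) {
    h <- abs(rnorm(1, 1.5, 0.3))
    make_window(pitch = rnorm(121),
                eyebrow = h * exp(-(-60:60)^2 / 72) + rnorm(121, 0, 0.1),
                segment_id = sprintf("0001-%04d", i), peak_height = h)
  })
  sc4 <- raise_scope(bump)
  expect_true(all(c(-4:4) %in% sc4$significant_positions))
  expect_true(all(abs(sc4$significant_positions) <= 16))

  expect_error(raise_scope(wins[1L]), "at least 2")
})
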