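test_that("frame tables round-trip through disk, preserving missing pitch", {
  d <- generate_dataset(synthetic_config(n_speakers = 2L,
                                         segments_per_speaker = 2L,
                                         segment_length_mean = 15,
                                         segment_length_sd = 0,
                                         missing_rate = 0.3, seed = 11))
  recs <- d$frames[seq_len(50L), ]
  expect_true(anyNA(recs$pitch))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frame_table(recs, path)
  back <- read_frame_table(path)
  expect_equal(back, recs, tolerance = 1e-12, ignore_attr = TRUE)
  # the NA token is literal in the file
  expect_true(any(grepl("\tNA$", readLines(path))))
})

test_that("read_frame_table validates schema and duplicates, applies column_map", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(speaker = "S01", episode = "0001", segment_id = "0001-0001",
                   frame = 0:1, eyebrow_height = c(0.5, 0.6),
                   lat_angle = 0, sag_angle = 0, pitch = c(1, NA))
  # missing mandatory column is named in the error
  utils::write.table(df[, -8L], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frame_table(path), "pitch")
  # foreign header loads through column_map
  df2 <- df
  names(df2)[names(df2) == "pitch"] <- "F0"
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frame_table(path), "pitch")
  back <- read_frame_table(path, column_map = c(pitch = "F0"))
  expect_identical(back$pitch, c(1, NA))
  # empty pitch cell becomes NA
  writeLines(c(paste(names(df), collapse = "\t"),
               "S01\t0001\t0001-0001\t0\t0.5\t0\t0\t"), path)
  expect_true(is.na(read_frame_table(path)$pitch))
  # duplicate (episode, frame, speaker)
  df3 <- rbind(df, df[1L, ])
  utils::write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_frame_table(path), "duplicate")
  expect_error(write_frame_table(df[0L, ], path), "empty")
})

test_that("parse_srt converts times to half-open frame intervals", {
  path <- withr::local_tempfile(fileext = ".srt")
  writeLines(c("1", "00:00:01,000 --> 00:00:02,000", "hello", "",
               "2372", "00:00:02,500 --> 00:00:04,250", "world", ""), path)
  seg <- parse_srt(path, fps = 30, episode = "0145")
  expect_equal(seg$start_frame, c(floor(1 * 30), floor(2.5 * 30)))
  expect_equal(seg$end_frame, c(floor(2 * 30), floor(4.25 * 30)))
  expect_identical(seg$segment_id[2L], "0145-2372")
  # frame conversion is monotone in time
  expect_true(all(diff(seg$start_frame) > 0))

  writeLines(character(), path)
  expect_identical(nrow(parse_srt(path, 30)), 0L)

  writeLines(c("1", "00:00:01.000 --> 00:00:02,000", "x", ""), path)
  expect_error(parse_srt(path, 30), "line 2")
  writeLines(c("1", "00:00:02,000 --> 00:00:02,000", "x", ""), path)
  expect_error(parse_srt(path, 30), "interval")
})

test_that("write_srt and parse_srt are inverse up to frame quantization", {
  seg <- data.frame(segment_id = sprintf("0007-%04d", 1:5),
                    episode = "0007",
                    start_frame = c(0L, 40L, 90L, 200L, 1000L),
                    end_frame = c(40L, 90L, 200L, 999L, 2000L),
                    text = letters[1:5])
  path <- withr::local_tempfile(fileext = ".srt")
  write_srt(seg, path, fps = 30)
  back <- parse_srt(path, fps = 30, episode = "0007")
  expect_equal(back$start_frame, seg$start_frame)
  expect_equal(back$end_frame, seg$end_frame)
  expect_identical(back$segment_id, seg$segment_id)
})

test_that("window tables span -60..60 in both orientations and round-trip", {
  set.seed(3)
  series <- list("0001-0001" = stats::setNames(rnorm(121), -60:60),
                 "0001-0002" = stats::setNames(c(rep(NA, 30), rnorm(61),
                                                 rep(NA, 30)), -60:60))
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_window_table(series, wide, "wide")
  write_window_table(series, long, "long")
  for (p in c(wide, long)) {
    back <- read_window_table(p)
    expect_length(back, 2L)
    for (id in names(series)) {
      expect_length(back[[id]], 121L)
      expect_equal(unname(back[[id]]), unname(series[[id]]),
                   tolerance = 1e-12)
    }
  }
  # sparse long table: unlisted positions are missing
  writeLines(c("segment_id\tposition\tvalue",
               "a\t0\t1", "a\t5\t2", "a\t-60\t3"), long)
  s <- read_window_table(long)[["a"]]
  expect_identical(sum(is.na(s)), 118L)
  # out-of-range position
  writeLines(c("segment_id\tposition\tvalue", "a\t61\t1"), long)
  expect_error(read_window_table(long), "position")
})
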