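test_that("positional summaries smooth pooled values with sane bands", {
  wins <- lapply(1:20, function(i)
    make_window(pitch = rep(1.7, 121), eyebrow = rep(0, 121),
                segment_id = sprintf("0001-%04d", i)))
  s <- positional_summary(wins, "pitch", k = 10)
  expect_true(all(abs(s$mean - 1.7) < 1e-6))
  expect_true(all(s$lo <= 1.7 + 1e-6 & s$hi >= 1.7 - 1e-6))
  expect_true(all(s$lo <= s$mean & s$mean <= s$hi))

  # duplicating every window leaves the smoothed means unchanged (up to
  # re-estimation of the smoothing parameter on the doubled sample)
  set.seed(2)
  wins2 <- lapply(1:25, function(i)
    make_window(pitch = sin((-60:60) / 20) + rnorm(121, 0, 0.2),
                segment_id = sprintf("0002-%04d", i)))
  s1 <- positional_summary(wins2, "pitch", k = 15)
  s2 <- positional_summary(c(wins2, wins2), "pitch", k = 15)
  expect_equal(s1$mean, s2$mean, tolerance = 0.02)
  # near-identical when the smoothing parameter is held fixed (duplication
  # doubles the data term against a fixed penalty, so exact equality is
  # not attainable for a penalized smooth)
  s1f <- positional_summary(wins2, "pitch", k = 15, sp = 1)
  s2f <- positional_summary(c(wins2, wins2), "pitch", k = 15, sp = 1)
  expect_equal(s1f$mean, s2f$mean, tolerance = 1e-4)

  # with a saturated unpenalized basis the smooth equals the
  # per-position means
  s3 <- positional_summary(wins2, "pitch", k = 121, sp = 0)
  permean <- rowMeans(vapply(wins2, `[[`, numeric(121L), "pitch"))
  expect_lt(max(abs(s3$mean - permean)), 1e-6)

  expect_error(positional_summary(wins2, "pitch", k = 150), "basis")
})

test_that("split_by_peak partitions at the threshold, boundary to high", {
  wins <- lapply(c(0.2, 1.6, 1.5, -0.4), function(h)
    make_window(pitch = rep(0, 121), peak_height = h,
                segment_id = sprintf("0001-%04d", round(100 * h))))
  sp <- split_by_peak(wins)
  expect_length(sp$low, 2L)
  expect_length(sp$high, 2L)
  expect_true(all(vapply(sp$high, `[[`, numeric(1), "peak_height") >= 1.5))

  set.seed(10)
  wins2 <- lapply(rnorm(1000), function(h)
    make_window(pitch = rep(0, 121), peak_height = h))
  frac <- length(split_by_peak(wins2)$high) / 1000
  expect_lt(abs(frac - stats::pnorm(1.5, lower.tail = FALSE)), 0.02)
})

test_that("fit_peak_model recovers noiseless coefficients and validates input", {
  set.seed(4)
  n <- 60L
  fits <- data.frame(segment_id = sprintf("s%03d", 1:n),
                     speaker = rep(c("a", "b", "c"), length.out = n),
                     region = "pre", window_size = 19L,
                     I = rnorm(n), A = runif(n, 0.2, 3),
                     f = runif(n, 0.2, 1.2), phi = runif(n, 0, 2),
                     r2 = 0.9, converged = TRUE,
                     n_missing_interpolated = 0L, skipped = FALSE,
                     skip_reason = NA_character_, stringsAsFactors = FALSE)
  peaks <- data.frame(segment_id = fits$segment_id, speaker = fits$speaker,
                      peak_height = 0.5 + 0.3 * fits$A - 0.2 * fits$f +
                        0.15 * fits$phi)
  m <- suppressWarnings(suppressMessages(fit_peak_model(fits, peaks)))
  expect_equal(unname(coef(m)), c(0.5, 0.3, -0.2, 0.15), tolerance = 1e-6)
  expect_identical(m$n_obs, n)
  expect_true(all(m$coefficients$p_value >= 0 & m$coefficients$p_value <= 1))

  one_sp <- fits; one_sp$speaker <- "a"
  expect_error(fit_peak_model(one_sp, peaks), "2 speakers")
  coll <- fits; coll$f <- 2 * coll$A
  expect_error(fit_peak_model(coll, peaks), "collinear")
  expect_error(fit_peak_model(fits[1:5, ], peaks), "10 observations")
})

test_that("with zero random-intercept variance the mixed fit equals OLS", {
  d <- generate_dataset(synthetic_config(n_speakers = 4L,
                                         segments_per_speaker = 40L,
                                         speaker_intercept_sd = 0,
                                         seed = 23))
  tf <- truth_fit_tables(d)
  mm <- fit_peak_model(tf$pre, tf$peaks)
  expect_lt(mm$random_intercept_variance, 1e-8)
  ols <- fit_peak_model(tf$pre, tf$peaks, random_intercept = FALSE)
  expect_equal(coef(mm), coef(ols), tolerance = 1e-6)
})

test_that("select_best_window minimizes ML AIC with a smallest-size tie rule", {
  d <- generate_dataset(synthetic_config(n_speakers = 3L,
                                         segments_per_speaker = 40L,
                                         seed = 31))
  tf <- truth_fit_tables(d)
  m <- fit_peak_model(tf$pre, tf$peaks)
  single <- select_best_window(list("19" = m))
  expect_identical(single$window_size, 19L)
  expect_identical(single$model, m)

  tie <- select_best_window(list("12" = m, "11" = m, "15" = m))
  expect_identical(tie$window_size, 11L)
  expect_identical(nrow(tie$criterion), 3L)
  expect_true(all(diff(tie$criterion$AIC) == 0))
})

test_that("combined model joins regions and respects a null pre-region", {
  cfg <- synthetic_config(n_speakers = 5L, segments_per_speaker = 60L,
                          coupling = c(intercept = 0.2, A_post = 0.25,
                                       f_post = 0.4),
                          seed = 47)
  d <- generate_dataset(cfg)
  tf <- truth_fit_tables(d)
  cm <- combined_model(tf$pre, tf$post, tf$peaks)
  tab <- cm$coefficients
  # pre-region coefficients are statistically indistinguishable from zero
  # (3 SE leaves headroom for testing three null terms at once)
  for (term in c("A_pre", "f_pre", "phi_pre")) {
    row <- tab[tab$term == term, ]
    expect_lt(abs(row$estimate), 3 * row$std_error)
  }
  # post-region effects are recovered
  expect_lt(abs(tab$estimate[tab$term == "A_post"] - 0.25),
            3 * tab$std_error[tab$term == "A_post"])
  expect_lt(abs(tab$estimate[tab$term == "f_post"] - 0.4),
            3 * tab$std_error[tab$term == "f_post"])

  # duplicating the data keeps point estimates, shrinks standard errors
  dup_pre <- rbind(tf$pre, transform(tf$pre, segment_id = paste0(segment_id, "b")))
  dup_post <- rbind(tf$post, transform(tf$post, segment_id = paste0(segment_id, "b")))
  dup_peaks <- rbind(tf$peaks, transform(tf$peaks, segment_id = paste0(segment_id, "b")))
  cm2 <- combined_model(dup_pre, dup_post, dup_peaks)
  # REML variance components shift slightly under duplication, so the GLS
  # estimates agree only approximately; the OLS route is exact
  expect_equal(coef(cm2), coef(cm), tolerance = 0.01)
  expect_true(all(cm2$coefficients$std_error < tab$std_error))
  ols1 <- combined_model(tf$pre, tf$post, tf$peaks, random_intercept = FALSE)
  ols2 <- combined_model(dup_pre, dup_post, dup_peaks,
                         random_intercept = FALSE)
  expect_equal(coef(ols2), coef(ols1), tolerance = 1e-9)

  other <- transform(tf$post, segment_id = paste0(segment_id, "x"))
  expect_error(combined_model(tf$pre, other, tf$peaks), "no segments")
})
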