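test_that("sine_value implements the baseline-shifted sinusoid", {
  expect_equal(sine_value(1, I = 0, A = 1, f = 0.25, phi = 0), 1)
  t <- seq(0, 2, by = 0.1)
  expect_equal(sine_value(t, 0, 1.3, 0.7, 1.2),
               -sine_value(t, 0, 1.3, 0.7, 0.2), tolerance = 1e-12)
  expect_equal(sine_value(t, 2, 0, 1, 0.3), rep(2, length(t)))
})

test_that("normalize_params canonicalizes without changing the curve", {
  expect_equal(normalize_params(0, -1, 0.5, 0.2),
               list(I = 0, A = 1, f = 0.5, phi = 1.2))
  expect_equal(normalize_params(0, 1, 0.5, 2.5),
               list(I = 0, A = 1, f = 0.5, phi = 0.5))
  expect_error(normalize_params(0, 1, 0, 0.5), "unidentifiable")

  set.seed(14)
  tg <- seq(0, 2, length.out = 100L)
  for (i in 1:50) {
    I <- rnorm(1); A <- rnorm(1, 0, 2); f <- rnorm(1, 0, 1.5); phi <- rnorm(1, 0, 4)
    if (f == 0) next
    p <- normalize_params(I, A, f, phi)
    expect_gte(p$A, 0); expect_gt(p$f, 0)
    expect_gte(p$phi, 0); expect_lt(p$phi, 2)
    expect_lt(max(abs(sine_value(tg, I, A, f, phi) -
                      sine_value(tg, p$I, p$A, p$f, p$phi))), 1e-10)
  }
})

test_that("fit_sine recovers noiseless parameters and flags constants", {
  set.seed(6)
  t <- (0:18) / 30
  for (i in 1:50) {
    truth <- list(I = runif(1, -1, 1), A = runif(1, 0.2, 3),
                  f = runif(1, 0.2, 1.2), phi = runif(1, 0, 2))
    y <- sine_value(t, truth$I, truth$A, truth$f, truth$phi)
    fit <- fit_sine(t, y)
    expect_true(fit$converged)
    p <- fit$params
    expect_lt(max(abs(c(p$I - truth$I, p$A - truth$A, p$f - truth$f,
                        phi_dist(p$phi, truth$phi)))), 1e-6)
    expect_lt(fit$sse, 1e-12)
  }
  cf <- fit_sine(t, rep(2.5, 19L))
  expect_equal(cf$params$A, 0)
  expect_equal(cf$params$I, 2.5)
  expect_true(cf$converged)
  expect_true(is.na(cf$params$f) && is.na(cf$params$phi))

  expect_error(fit_sine(t[1:4], rnorm(4)), "at least 5")
  expect_error(fit_sine(rev(t), rnorm(19)), "increasing")
  expect_error(fit_sine(t, c(rnorm(18), NA)), "gap-free")
})

test_that("sine_fit methods behave like a fitted-model object", {
  t <- (0:16) / 30
  y <- sine_value(t, 0.3, 1.1, 0.9, 0.6) + c(rep(0, 16), 0.2)
  fit <- fit_sine(t, y)
  expect_s3_class(fit, "sine_fit")
  expect_named(coef(fit), c("I", "A", "f", "phi"))
  expect_equal(unname(predict(fit)), unname(fitted(fit)), tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_output(print(fit), "r2")
})

test_that("r_squared follows the 1 - SSE/SST definition", {
  y <- c(0, 2, 2, 4)              # SST = 8
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4L)), 0)
  expect_equal(r_squared(y, c(1, 3, 2, 4)), 1 - 2 / 8)  # SSE = 2
  expect_error(r_squared(rep(1, 4L), rep(1, 4L)), "undefined")
})

test_that("phase categories partition [0, 2) into half-open quarters", {
  expect_identical(phase_category(0.24), "high_rising")
  expect_identical(phase_category(1.04), "low_falling")
  expect_identical(phase_category(0.5), "high_falling")
  expect_identical(phase_category(1.999), "low_rising")
  expect_identical(phase_category(c(0, 0.499, 1, 1.5)),
                   c("high_rising", "high_rising", "low_falling",
                     "low_rising"))
  expect_error(phase_category(2), "\\[0, 2\\)")
  expect_error(phase_category(-0.1), "\\[0, 2\\)")
})

test_that("fit_region slices the window per region convention", {
  # plant distinguishable sines on the two sides of the peak
  pre <- list(I = 0.1, A = 1.4, f = 0.5, phi = 0.3)
  post <- list(I = -0.2, A = 2.1, f = 1.0, phi = 1.7)
  g <- generate_pitch_window(pre, post, pre_size = 17L, post_size = 17L,
                             missing_rate = 0, walk_sd = 0)
  w <- make_window(pitch = g$values)

  fpre <- fit_region(w, "pre", 17L)
  # pre region covers positions -16..0: time origin at position -16
  expect_identical(fpre$n, 17L)
  y_expected <- sine_value((0:16) / 30, pre$I, pre$A, pre$f, pre$phi)
  expect_equal(fpre$values, y_expected, tolerance = 1e-10)

  fpost <- fit_region(w, "post", 17L)
  expect_equal(fpost$values,
               sine_value((0:16) / 30, g$post$I, g$post$A, g$post$f,
                          g$post$phi), tolerance = 1e-10)
  # both parameter sets recovered from their windows
  expect_lt(abs(fpre$params$f - pre$f), 1e-6)
  expect_lt(abs(fpost$params$f - post$f), 1e-6)
  expect_lt(phi_dist(fpost$params$phi, post$phi), 1e-6)

  # insufficient coverage yields a skip marker, not an error
  w2 <- w
  w2$pitch[w2$positions >= -16 & w2$positions <= -5] <- NA
  sk <- fit_region(w2, "pre", 17L)
  expect_s3_class(sk, "sine_skip")
  expect_match(sk$reason, "coverage")
})

test_that("window-size sweeps are deterministic and keep skip markers", {
  d <- generate_dataset(synthetic_config(n_speakers = 1L,
                                         segments_per_speaker = 3L,
                                         missing_rate = 0.4, seed = 17))
  windows <- build_windows(d$frames)
  tab <- sweep_window_sizes(windows, "post", sizes = c(10L, 15L, 20L))
  expect_identical(nrow(tab), 9L)
  expect_true(all(tab$window_size %in% c(10L, 15L, 20L)))
  tab2 <- sweep_window_sizes(windows, "post", sizes = c(10L, 15L, 20L))
  expect_identical(tab, tab2)

  # mean r2 computed incrementally equals the batch aggregate
  ok <- !tab$skipped & tab$converged & tab$window_size == 20L
  batch <- mean(tab$r2[ok])
  inc <- 0
  n <- 0L
  for (r in tab$r2[ok]) { inc <- inc + r; n <- n + 1L }
  expect_equal(inc / n, batch, tolerance = 1e-12)

  expect_identical(nrow(sweep_window_sizes(list(), "pre")), 0L)
  expect_error(sweep_window_sizes(windows, "pre", sizes = 61L))
})
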