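# Baseline-shifted sinusoid: y = I + A * sin(2*pi*f*t + phi*pi)
#   I   baseline shift (pitch units)
#   A   amplitude, >= 0
#   f   ordinary frequency, cycles per second
#   phi phase in units of pi radians, in [0, 2)
# Time is in seconds, with t = 0 at the first frame of the fitted region.

#' Evaluate the baseline-shifted sinusoid
#'
#' Computes `I + A * sin(2 * pi * f * t + phi * pi)`.
#'
#' @param t Time in seconds (vectorized).
#' @param I Baseline shift.
#' @param A Amplitude.
#' @param f Ordinary frequency in cycles per second.
#' @param phi Phase in units of pi radians.
#' @return Numeric vector of the same length as `t`.
#' @export
sine_value <- function(t, I, A, f, phi) {
  I + A * sin(2 * pi * f * t + phi * pi)
}

#' Canonicalize sinusoid parameters
#'
#' Maps an unconstrained `(I, A, f, phi)` to the unique equivalent set with
#' `A >= 0`, `f > 0`, `phi` in `[0, 2)`; the curve is pointwise unchanged.
#' Uses the identities `sin(-x) = -sin(x)` (negative frequency) and
#' `-sin(x) = sin(x + pi)` (negative amplitude), then wraps the phase
#' modulo 2.
#'
#' @param I,A,f,phi Raw parameter values.
#' @return A named list with components `I`, `A`, `f`, `phi`.
#' @export
normalize_params <- function(I, A, f, phi) {
  if (!is.finite(f) || f == 0) {
    stop("frequency f = 0 is unidentifiable", call. = FALSE)
  }
  if (f < 0) {
    # A sin(2pi f t + phi pi) = -A sin(2pi (-f) t - phi pi)
    f <- -f
    A <- -A
    phi <- -phi
  }
  if (A < 0) {
    A <- -A
    phi <- phi + 1
  }
  phi <- phi %% 2
  list(I = I, A = A, f = f, phi = phi)
}

#' Coefficient of determination
#'
#' `1 - SSE / SST` with the total sum of squares about the mean of
#' `observed`. Equals 1 for a perfect fit and can be negative for fits worse
#' than the mean.
#'
#' @param observed Observed values.
#' @param fitted Fitted values (same length).
#' @return A scalar `<= 1`.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted))
  sst <- sum((observed - mean(observed))^2)
  if (sst <= .Machine$double.eps) {
    stop("zero total sum of squares: r-squared undefined", call. = FALSE)
  }
  1 - sum((observed - fitted)^2) / sst
}

#' Phase category of a sinusoid
#'
#' The four quarters of the cycle, by where the waveform starts:
#' `high_rising` for `0 <= phi < 0.5`, `high_falling` for `0.5 <= phi < 1`,
#' `low_falling` for `1 <= phi < 1.5`, `low_rising` for `1.5 <= phi < 2`.
#'
#' @param phi Phase in units of pi radians, in `[0, 2)` (vectorized).
#' @return Character vector of category labels.
#' @export
phase_category <- function(phi) {
  if (any(is.na(phi)) || any(phi < 0 | phi >= 2)) {
    stop("phi must lie in [0, 2); normalize parameters first", call. = FALSE)
  }
  labels <- c("high_rising", "high_falling", "low_falling", "low_rising")
  labels[pmin(4L, floor(phi / 0.5) + 1L)]
}

# Frequency search range (cycles/s) and seed frequencies spanning sub-cycle
# to multi-cycle excursions over a 10-20 frame window.
.f_bounds <- c(0.05, 5)
.start_freqs <- c(0.3, 0.6, 1.0, 1.6, 2.4)

# Profiled (variable-projection) SSE: for fixed f the model
# y = I + a sin(2 pi f t) + b cos(2 pi f t) is linear in (I, a, b).
.vp_solve <- function(f, t, y) {
  w <- 2 * pi * f * t
  X <- cbind(1, sin(w), cos(w))
  fit <- stats::.lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

.vp_sse <- function(f, t, y) .vp_solve(f, t, y)$sse

#' Fit the baseline-shifted sinusoid by multi-start profiled least squares
#'
#' Least-squares estimation of `(I, A, f, phi)` exploiting that for fixed
#' frequency the model `y = I + a sin(2 pi f t) + b cos(2 pi f t)` is linear
#' in `(I, a, b)`: the residual sum of squares is profiled over `f` by 1-D
#' `nlminb` from each start frequency (defaults 0.3, 0.6, 1.0, 1.6, 2.4
#' cycles/s, each searched within its own bracket between neighboring
#' starts, overall bounds 0.05-5), and the winner is polished by one
#' `stats::nls` run (`"port"` algorithm, amplitude bounded to
#' `[0, 5 * range]`). The multi-start frequency search targets the minima
#' reachable from physiologically plausible pitch-excursion rates; the
#' phase needs no start grid because it is solved exactly at every
#' frequency. Candidates whose amplitude exceeds the `5 * range` bound
#' (near-linear giant arcs at very low frequency) are only used if no
#' admissible candidate exists. Parameters are canonicalized with
#' [normalize_params()]. Constant input short-circuits to `A = 0`,
#' `I = mean` with unidentifiable frequency and phase.
#'
#' @param times Strictly increasing time points (seconds).
#' @param values Gap-free numeric observations (same length, `>= 5`).
#' @param starts Start frequencies in cycles/s.
#' @param select_mask Optional logical vector marking the genuinely
#'   observed points. When some values are interpolated, competing local
#'   minima are compared on the observed points only — interpolated
#'   segments sag below a true sine and can otherwise tip the choice
#'   toward a spurious frequency basin. Fitting itself always uses all
#'   values.
#' @return An object of class `sine_fit` with components `params` (named
#'   list `I`, `A`, `f`, `phi`), `r2`, `sse`, `converged`, `n`,
#'   `fitted.values`, `residuals`, `times`, `values`.
#' @examples
#' t <- (0:16) / 30
#' y <- sine_value(t, I = 0.2, A = 1.5, f = 0.8, phi = 0.4)
#' fit <- fit_sine(t, y)
#' coef(fit)
#' @export
fit_sine <- function(times, values, starts = .start_freqs,
                     select_mask = NULL) {
  stopifnot(length(times) == length(values))
  if (length(times) < 5L) stop("need at least 5 points", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(values)) stop("values must be gap-free (interpolate first)", call. = FALSE)

  rng <- max(values) - min(values)
  n <- length(values)
  if (rng <= .Machine$double.eps) {
    fitted <- rep(mean(values), n)
    return(structure(list(
      params = list(I = mean(values), A = 0, f = NA_real_, phi = NA_real_),
      r2 = NA_real_, sse = 0, converged = TRUE, identifiable = FALSE,
      n = n, fitted.values = fitted, residuals = values - fitted,
      times = times, values = values), class = "sine_fit"))
  }

  # profile the SSE densely over the band reachable from the start
  # frequencies (up to 3 cycles/s, the outer basin of the 2.4 start) and
  # refine the best local minima; frequencies above this band would let a
  # 4-parameter sine chase interpolation wiggles in 10-20 point windows
  f_hi <- min(.f_bounds[2L], max(3, max(starts) * 1.25))
  f_grid <- sort(unique(c(starts, seq(.f_bounds[1L], f_hi, length.out = 50L))))
  sse_grid <- vapply(f_grid, .vp_sse, numeric(1L), t = times, y = values)
  is_min <- c(TRUE, diff(sse_grid) < 0) & c(diff(sse_grid) > 0, TRUE)
  cand <- f_grid[is_min][order(sse_grid[is_min])]
  cand <- utils::head(cand, 3L)
  step <- diff(range(f_grid)) / 49
  A_max <- 5 * rng
  if (is.null(select_mask) || all(select_mask)) {
    sel <- rep(TRUE, n)
  } else {
    stopifnot(length(select_mask) == n)
    sel <- select_mask
  }
  sols <- lapply(cand, function(f0) {
    opt <- stats::nlminb(f0, .vp_sse, t = times, y = values,
                         lower = max(.f_bounds[1L], f0 - 2 * step),
                         upper = min(f_hi, f0 + 2 * step),
                         control = list(abs.tol = 0, rel.tol = 1e-12,
                                        iter.max = 200))
    sol <- .vp_solve(opt$par, times, values)
    pred <- sol$coef[1L] + sol$coef[2L] * sin(2 * pi * opt$par * times) +
      sol$coef[3L] * cos(2 * pi * opt$par * times)
    list(f = opt$par, sse = sol$sse,
         sse_sel = sum((values[sel] - pred[sel])^2), coef = sol$coef,
         A = sqrt(sol$coef[2L]^2 + sol$coef[3L]^2),
         converged = opt$convergence == 0)
  })
  # prefer admissible candidates (amplitude within the 5 * range bound);
  # very low frequencies can explain a drifting window with an absurdly
  # large near-linear sine arc, which the bound rules out. An essentially
  # exact fit (SSE at machine zero relative to SST) is genuine signal from
  # a window near a flat sine extremum, not overfit, and is kept even when
  # its amplitude exceeds the bound.
  sst <- sum((values - mean(values))^2)
  adm <- vapply(sols, function(s)
    s$A <= A_max || s$sse <= 1e-12 * sst, logical(1L))
  pool <- if (any(adm)) sols[adm] else sols
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1L), "sse_sel"))]]
  best_sse <- best$sse
  converged <- best$converged
  I_hat <- best$coef[1L]
  A_hat <- if (best$sse <= 1e-12 * sst) best$A else min(best$A, A_max)
  phi_hat <- atan2(best$coef[3L], best$coef[2L]) / pi
  params <- normalize_params(I_hat, A_hat, best$f, phi_hat)

  cur_sse <- sum((values - sine_value(times, params$I, params$A, params$f,
                                      params$phi))^2)
  # one nls polish from the profiled solution (joint refinement of all four)
  polish <- tryCatch(
    stats::nls(y ~ I + A * sin(2 * pi * f * t + phi * pi),
               data = data.frame(t = times, y = values),
               start = list(I = params$I, A = params$A, f = params$f,
                            phi = params$phi),
               algorithm = "port",
               lower = c(I = -Inf, A = 0, f = .f_bounds[1L], phi = -Inf),
               upper = c(I = Inf, A = 5 * rng, f = f_hi, phi = Inf),
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(stats::residuals(polish)^2) <= cur_sse) {
    cf <- stats::coef(polish)
    params <- normalize_params(cf[["I"]], cf[["A"]], cf[["f"]], cf[["phi"]])
    converged <- TRUE
  }
  fitted <- sine_value(times, params$I, params$A, params$f, params$phi)
  res <- values - fitted
  structure(list(
    params = params,
    r2 = r_squared(values, fitted),
    sse = sum(res^2),
    converged = converged,
    identifiable = TRUE,
    n = n,
    fitted.values = fitted,
    residuals = res,
    times = times,
    values = values), class = "sine_fit")
}

#' @export
coef.sine_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
print.sine_fit <- function(x, ...) {
  p <- x$params
  cat("Baseline-shifted sinusoid fit (", x$n, " points",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  if (!x$identifiable) {
    cat("  constant signal: I =", format(p$I, digits = 4),
        " A = 0 (frequency/phase unidentifiable)\n")
  } else {
    cat(sprintf("  I = %.4g  A = %.4g  f = %.4g cycles/s  phi = %.4g pi rad (%s)\n",
                p$I, p$A, p$f, p$phi, phase_category(p$phi)))
    cat(sprintf("  r2 = %.4f\n", x$r2))
  }
  invisible(x)
}

#' @export
summary.sine_fit <- function(object, ...) {
  print(object)
  cat("  SSE =", format(object$sse, digits = 6), "\n")
  invisible(object)
}

#' @export
predict.sine_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.list(newdata)) newdata$t
       else newdata
  if (!object$identifiable) return(rep(object$params$I, length(t)))
  p <- object$params
  sine_value(t, p$I, p$A, p$f, p$phi)
}

#' @export
fitted.sine_fit <- function(object, ...) object$fitted.values

#' @export
residuals.sine_fit <- function(object, ...) object$residuals

#' @export
plot.sine_fit <- function(x, n_grid = 200, ...) {
  graphics::plot(x$times, x$values, pch = 16,
                 xlab = "time (s)", ylab = "value", ...)
  tg <- seq(min(x$times), max(x$times), length.out = n_grid)
  graphics::lines(tg, predict(x, tg), col = "red3", lwd = 2)
  invisible(x)
}

#' Fit the sinusoid to the pre- or post-peak region of a window
#'
#' The pre region covers positions `-(window_size - 1) ... 0` and the post
#' region positions `0 ... (window_size - 1)`; both include the peak frame.
#' Missing pitch values inside the region are filled by
#' [interpolate_missing()] before fitting; time is
#' `(position - first position) / fps` seconds. Regions with less than
#' `min_coverage` non-missing values are skipped, returning a `sine_skip`
#' marker instead of raising an error.
#'
#' @param window A `segment_window` (see [extract_window()]).
#' @param region `"pre"` or `"post"`.
#' @param window_size Number of frames fitted, including the peak.
#' @param fps Frames per second (default 30).
#' @param min_coverage Minimum fraction of non-missing positions (default
#'   0.75).
#' @return A `sine_fit` with extra fields `segment_id`, `speaker`, `region`,
#'   `window_size`, `n_missing_interpolated`, or a `sine_skip` list with a
#'   `reason`.
#' @export
fit_region <- function(window, region = c("pre", "post"), window_size,
                       fps = 30, min_coverage = 0.75) {
  region <- match.arg(region)
  stopifnot(window_size >= 5)
  pos <- if (region == "pre") seq.int(-(window_size - 1L), 0L)
         else seq.int(0L, window_size - 1L)
  idx <- match(pos, window$positions)
  if (anyNA(idx)) {
    stop("window does not span the requested region", call. = FALSE)
  }
  y <- window$pitch[idx]
  n_ok <- sum(!is.na(y))
  skip <- function(reason) {
    structure(list(segment_id = window$segment_id, speaker = window$speaker,
                   region = region, window_size = window_size,
                   reason = reason), class = "sine_skip")
  }
  if (n_ok < min_coverage * length(pos)) {
    return(skip(sprintf("coverage %d/%d below %.0f%%", n_ok, length(pos),
                        100 * min_coverage)))
  }
  if (n_ok < 2L) return(skip("fewer than 2 non-missing pitch values"))
  # interpolate over the whole window, not just the region slice, so a gap
  # at the region edge is bridged from real neighboring values rather than
  # extended flat
  y_filled <- interpolate_missing(window$pitch)[idx]
  t <- (pos - pos[1L]) / fps
  fit <- fit_sine(t, y_filled, select_mask = !is.na(y))
  fit$segment_id <- window$segment_id
  fit$speaker <- window$speaker
  fit$region <- region
  fit$window_size <- as.integer(window_size)
  fit$n_missing_interpolated <- length(pos) - n_ok
  fit
}

#' @export
print.sine_skip <- function(x, ...) {
  cat("Skipped sinusoid fit:", x$segment_id, x$region,
      paste0("(size ", x$window_size, "):"), x$reason, "\n")
  invisible(x)
}

.fit_row <- function(f) {
  if (inherits(f, "sine_skip")) {
    data.frame(segment_id = f$segment_id, speaker = f$speaker,
               region = f$region, window_size = f$window_size,
               I = NA_real_, A = NA_real_, f = NA_real_, phi = NA_real_,
               r2 = NA_real_, converged = NA,
               n_missing_interpolated = NA_integer_,
               skipped = TRUE, skip_reason = f$reason,
               stringsAsFactors = FALSE)
  } else {
    p <- f$params
    data.frame(segment_id = f$segment_id, speaker = f$speaker,
               region = f$region, window_size = f$window_size,
               I = p$I, A = p$A, f = p$f, phi = p$phi,
               r2 = f$r2, converged = f$converged,
               n_missing_interpolated = f$n_missing_interpolated,
               skipped = FALSE, skip_reason = NA_character_,
               stringsAsFactors = FALSE)
  }
}

#' Fit one region at one window size across many windows
#'
#' @param windows List of `segment_window` objects.
#' @param region `"pre"` or `"post"`.
#' @param window_size Frames fitted, including the peak.
#' @param fps Frames per second.
#' @param min_coverage Minimum non-missing fraction per region.
#' @return A `data.frame` with one row per window: the normalized parameters
#'   `I`, `A`, `f`, `phi`, `r2`, `converged`, `n_missing_interpolated`, plus
#'   skip markers (`skipped`, `skip_reason`).
#' @export
fit_table <- function(windows, region, window_size, fps = 30,
                      min_coverage = 0.75) {
  if (!length(windows)) {
    return(data.frame(segment_id = character(), speaker = character(),
                      region = character(), window_size = integer(),
                      I = numeric(), A = numeric(), f = numeric(),
                      phi = numeric(), r2 = numeric(), converged = logical(),
                      n_missing_interpolated = integer(),
                      skipped = logical(), skip_reason = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(windows, function(w)
    .fit_row(fit_region(w, region, window_size, fps, min_coverage)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep window sizes for one region
#'
#' Fits every window at every size; deterministic given the inputs, so
#' re-running yields an identical table.
#'
#' @param windows List of `segment_window` objects.
#' @param region `"pre"` or `"post"`.
#' @param sizes Integer vector of window sizes (default `10:20`; must lie in
#'   5..60).
#' @param fps Frames per second.
#' @param min_coverage Minimum non-missing fraction per region.
#' @return Row-bound [fit_table()] results over all sizes.
#' @export
sweep_window_sizes <- function(windows, region, sizes = 10:20, fps = 30,
                               min_coverage = 0.75) {
  stopifnot(all(sizes >= 5 & sizes <= 60))
  if (!length(windows)) {
    return(fit_table(list(), region, sizes[1L]))
  }
  out <- do.call(rbind, lapply(sizes, function(s)
    fit_table(windows, region, s, fps, min_coverage)))
  rownames(out) <- NULL
  out
}
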