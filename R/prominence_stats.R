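# Positional summaries and the mixed models linking sinusoid parameters to
# brow-peak magnitude.

#' Smoothed positional summary curve
#'
#' Pools values at each window position over all windows and fits a
#' penalized cubic-spline smooth (`mgcv::gam`, `value ~ s(position, k)`),
#' returning the smoothed mean with pointwise 95% bands from the smoother's
#' standard errors.
#'
#' @param windows List of `segment_window` objects.
#' @param signal `"eyebrow"` or `"pitch"`.
#' @param k Spline basis dimension (default 30).
#' @param subset_rule Optional predicate `function(window) -> logical`
#'   applied before pooling.
#' @param sp Smoothing parameter passed to [mgcv::gam()]; `NULL` (default)
#'   estimates it from the data, `0` disables penalization so the smooth
#'   interpolates the per-position least-squares fit.
#' @return An object of class `positional_summary`: a `data.frame` with
#'   columns `position`, `mean`, `lo`, `hi` and attributes `k`, `signal`,
#'   `n_windows`.
#' @export
positional_summary <- function(windows, signal = c("eyebrow", "pitch"),
                               k = 30, subset_rule = NULL, sp = NULL) {
  signal <- match.arg(signal)
  if (!is.null(subset_rule)) {
    windows <- Filter(subset_rule, windows)
  }
  if (!length(windows)) stop("no windows after subsetting", call. = FALSE)
  long <- do.call(rbind, lapply(windows, function(w) {
    keep <- !is.na(w[[signal]])
    data.frame(position = w$positions[keep], value = w[[signal]][keep])
  }))
  n_pos <- length(unique(long$position))
  if (n_pos < k) {
    stop("basis dimension k = ", k, " too large for ", n_pos,
         " distinct positions", call. = FALSE)
  }
  fit <- mgcv::gam(value ~ s(position, k = k, bs = "cr"), data = long,
                   sp = sp)
  grid <- data.frame(position = sort(unique(long$position)))
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  out <- data.frame(position = grid$position,
                    mean = as.numeric(pr$fit),
                    lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                    hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  structure(out, k = k, signal = signal, n_windows = length(windows),
            class = c("positional_summary", "data.frame"))
}

#' @export
plot.positional_summary <- function(x, ...) {
  graphics::plot(x$position, x$mean, type = "n",
                 ylim = range(c(x$lo, x$hi)),
                 xlab = "position (frames from eyebrow peak)",
                 ylab = paste0(attr(x, "signal"), " (z)"), ...)
  graphics::polygon(c(x$position, rev(x$position)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$position, x$mean, col = "steelblue4", lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Split windows by eyebrow-peak height
#'
#' Partitions windows at `threshold` standard deviations of peak height;
#' peaks exactly at the threshold go to the high set.
#'
#' @param windows List of `segment_window` objects (peak heights in
#'   z-units).
#' @param threshold Split point in standard deviations (default 1.5).
#' @return A list with elements `low` and `high`.
#' @export
split_by_peak <- function(windows, threshold = 1.5) {
  ph <- vapply(windows, function(w) w$peak_height, numeric(1L))
  list(low = windows[ph < threshold], high = windows[ph >= threshold])
}

.lmer_coef_table <- function(model) {
  sm <- summary(model)$coefficients
  data.frame(term = rownames(sm),
             estimate = sm[, "Estimate"],
             std_error = sm[, "Std. Error"],
             df = sm[, "df"],
             t_value = sm[, "t value"],
             p_value = sm[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.make_peak_model <- function(data, predictors, region, window_size,
                             random_intercept = TRUE) {
  if (nrow(data) < 10L) {
    stop("need at least 10 observations, got ", nrow(data), call. = FALSE)
  }
  if (random_intercept && length(unique(data$speaker)) < 2L) {
    stop("degenerate grouping: need at least 2 speakers for a random ",
         "intercept", call. = FALSE)
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(predictors) + 1L) {
    stop("collinear predictors: fixed-effect design is rank deficient",
         call. = FALSE)
  }
  rhs <- paste(predictors, collapse = " + ")
  if (random_intercept) {
    fml <- stats::as.formula(paste("peak_height ~", rhs, "+ (1 | speaker)"))
    model <- lmerTest::lmer(fml, data = data, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(model))
    ri_var <- vc$vcov[vc$grp == "speaker"]
    res_var <- vc$vcov[vc$grp == "Residual"]
    coefs <- .lmer_coef_table(model)
  } else {
    fml <- stats::as.formula(paste("peak_height ~", rhs))
    model <- stats::lm(fml, data = data)
    sm <- summary(model)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                        std_error = sm[, 2L],
                        df = stats::df.residual(model),
                        t_value = sm[, 3L], p_value = sm[, 4L],
                        row.names = NULL, stringsAsFactors = FALSE)
    ri_var <- 0
    res_var <- summary(model)$sigma^2
  }
  structure(list(model = model, coefficients = coefs,
                 random_intercept_variance = ri_var,
                 residual_variance = res_var,
                 n_obs = nrow(data), region = region,
                 window_size = window_size,
                 predictors = predictors,
                 data = data),
            class = "peak_model")
}

#' Mixed model for brow-peak magnitude from sinusoid parameters
#'
#' Fits `peak_height ~ predictors + (1 | speaker)` by REML
#' (`lmerTest::lmer`) and reports estimate, standard error,
#' Satterthwaite degrees of freedom, t and p per fixed effect, plus the
#' random-intercept and residual variances. Skipped and non-converged
#' sinusoid fits are excluded.
#'
#' @param fits A [fit_table()] `data.frame` for one region and window size.
#' @param peaks A `data.frame` with `segment_id`, `speaker`, `peak_height`
#'   (z-units). If `NULL`, `fits` must already carry a `peak_height` column.
#' @param predictors Character subset of `c("I", "A", "f", "phi")` (default
#'   excludes the baseline shift, whose effect the separate-region tables
#'   omit; include `"I"` to model it).
#' @param random_intercept If `FALSE`, fits ordinary least squares without
#'   the speaker term (useful for degenerate designs).
#' @return An object of class `peak_model`.
#' @export
fit_peak_model <- function(fits, peaks = NULL,
                           predictors = c("A", "f", "phi"),
                           random_intercept = TRUE) {
  stopifnot(all(predictors %in% c("I", "A", "f", "phi")))
  d <- fits
  if ("skipped" %in% names(d)) d <- d[!d$skipped & d$converged, , drop = FALSE]
  if (!is.null(peaks)) {
    d <- merge(d, peaks[, c("segment_id", "peak_height")], by = "segment_id")
  }
  d <- d[stats::complete.cases(d[, c(predictors, "peak_height", "speaker")]), ,
         drop = FALSE]
  region <- if ("region" %in% names(d) && nrow(d)) d$region[1L] else NA_character_
  size <- if ("window_size" %in% names(d) && nrow(d)) d$window_size[1L] else NA_integer_
  .make_peak_model(d, predictors, region, size, random_intercept)
}

#' @export
print.peak_model <- function(x, digits = 3, ...) {
  cat("Mixed model for eyebrow-peak magnitude (",
      x$region, if (!is.na(x$window_size)) paste0(", window ", x$window_size),
      ", n = ", x$n_obs, ")\n", sep = "")
  tab <- x$coefficients
  tab[, -1L] <- lapply(tab[, -1L], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  cat("Random intercept (speaker) variance:",
      format(x$random_intercept_variance, digits = 3),
      " residual variance:", format(x$residual_variance, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.peak_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.peak_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Select the window size with the best peak model
#'
#' Refits each candidate by maximum likelihood and picks the minimum-AIC
#' model (REML criteria are not comparable across fixed-effect structures;
#' here the structure is constant, but the ML refit keeps the criterion
#' conventional). Ties go to the smallest window size.
#'
#' @param models Named list of `peak_model` objects; names are window
#'   sizes.
#' @return A list with `window_size`, `model`, and the full `criterion`
#'   table.
#' @export
select_best_window <- function(models) {
  stopifnot(length(models) >= 1L)
  sizes <- as.integer(names(models))
  if (anyNA(sizes)) {
    sizes <- vapply(models, function(m) as.integer(m$window_size), integer(1L))
  }
  aic <- vapply(models, function(m) {
    if (inherits(m$model, "merMod")) stats::AIC(lme4::refitML(m$model))
    else stats::AIC(m$model)
  }, numeric(1L))
  crit <- data.frame(window_size = sizes, AIC = aic, row.names = NULL)
  o <- order(crit$AIC, crit$window_size)
  best <- o[1L]
  list(window_size = sizes[best], model = models[[best]], criterion = crit)
}

#' Combined pre/post-region model of brow-peak magnitude
#'
#' Inner-joins the pre- and post-region fit tables on segment id (suffixing
#' parameters `_pre` / `_post`) and fits the mixed model with the
#' region-specific predictor sets — by default the variables significant in
#' the separate models: amplitude, frequency and phase from the pre region,
#' amplitude and frequency from the post region.
#'
#' @param pre_fits,post_fits [fit_table()] results (typically window sizes
#'   19 and 17).
#' @param peaks `data.frame` with `segment_id`, `speaker`, `peak_height`.
#' @param predictors_pre,predictors_post Parameter subsets per region.
#' @param random_intercept See [fit_peak_model()].
#' @return A `peak_model` with region `"combined"`.
#' @export
combined_model <- function(pre_fits, post_fits, peaks,
                           predictors_pre = c("A", "f", "phi"),
                           predictors_post = c("A", "f"),
                           random_intercept = TRUE) {
  keep <- function(d) d[!d$skipped & d$converged, , drop = FALSE]
  pre <- keep(pre_fits)[, c("segment_id", "speaker", "I", "A", "f", "phi")]
  post <- keep(post_fits)[, c("segment_id", "I", "A", "f", "phi")]
  d <- merge(pre, post, by = "segment_id", suffixes = c("_pre", "_post"))
  if (!nrow(d)) {
    stop("no segments present in both fit tables", call. = FALSE)
  }
  d <- merge(d, peaks[, c("segment_id", "peak_height")], by = "segment_id")
  predictors <- c(paste0(predictors_pre, "_pre"),
                  paste0(predictors_post, "_post"))
  d <- d[stats::complete.cases(d[, c(predictors, "peak_height")]), , drop = FALSE]
  m <- .make_peak_model(d, predictors, "combined", NA_integer_,
                        random_intercept)
  m$window_size <- NA_integer_
  m
}
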