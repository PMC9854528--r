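# End-to-end orchestration: frames + segments -> windows -> scope test ->
# sinusoid sweeps -> positional summaries -> mixed models -> report.

#' Pipeline configuration
#'
#' @param fps Frames per second (default 30).
#' @param half_width Analysis-window half-width in frames (default 60).
#' @param sweep_sizes Window sizes swept for both regions (default 10:20).
#' @param pre_size,post_size Window sizes of the reported pre/post models
#'   (defaults 19, 17).
#' @param peak_split Peak-height split point in SD units (default 1.5).
#' @param alpha Significance level of the scope test (default 0.05).
#' @param correction Multiplicity correction of the scope test (default
#'   `"holm"`).
#' @param gam_k Basis dimension of positional smooths (default 30 for the
#'   full sample, 10 for the peak-split subsets, matching the reported
#'   curves).
#' @param gam_k_split Basis dimension for the split subsets (default 10).
#' @param standardize Standardize eyebrow height and pitch per speaker
#'   before analysis (default `TRUE`; synthetic corpora are generated in
#'   z-units already and are analyzed with `standardize = FALSE`).
#' @param min_coverage Minimum non-missing fraction per fitted region.
#' @param predictors_pre,predictors_post,predictors_combined_pre,predictors_combined_post
#'   Fixed-effect sets of the separate and combined models.
#' @param seed Seed recorded in the bundle (the pipeline itself is
#'   deterministic; the seed feeds any upstream simulation).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 30, half_width = 60L, sweep_sizes = 10:20,
                            pre_size = 19L, post_size = 17L,
                            peak_split = 1.5, alpha = 0.05,
                            correction = "holm", gam_k = 30,
                            gam_k_split = 10, standardize = TRUE,
                            min_coverage = 0.75,
                            predictors_pre = c("A", "f", "phi"),
                            predictors_post = c("A", "f", "phi"),
                            predictors_combined_pre = c("A", "f", "phi"),
                            predictors_combined_post = c("A", "f"),
                            seed = 1L) {
  stopifnot(fps > 0, half_width >= 1, all(sweep_sizes >= 5 & sweep_sizes <= 60),
            pre_size %in% 5:60, post_size %in% 5:60)
  structure(list(fps = fps, half_width = as.integer(half_width),
                 sweep_sizes = as.integer(sweep_sizes),
                 pre_size = as.integer(pre_size),
                 post_size = as.integer(post_size),
                 peak_split = peak_split, alpha = alpha,
                 correction = correction, gam_k = gam_k,
                 gam_k_split = gam_k_split, standardize = standardize,
                 min_coverage = min_coverage,
                 predictors_pre = predictors_pre,
                 predictors_post = predictors_post,
                 predictors_combined_pre = predictors_combined_pre,
                 predictors_combined_post = predictors_combined_post,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(unclass(config)))], file = tmp)
  unname(tools::md5sum(tmp))
}

.safe_model <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "model_unavailable")
  })
}

#' @export
print.model_unavailable <- function(x, ...) {
  cat("no model:", x$error, "\n")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Stages: per-speaker standardization (optional), segment attachment, peak
#' finding and window extraction, the positional scope test, pre/post
#' sinusoid sweeps, positional summaries for the full sample and the
#' peak-height split, mixed models at the reporting window sizes, the
#' window-size selection table, and the combined-region model. A stage that
#' cannot be fitted (e.g. all pitch missing) yields a `model_unavailable`
#' marker rather than aborting the run.
#'
#' @param frames Frame table (see [read_frame_table()]).
#' @param segments Segment table (see [parse_srt()]); `NULL` if `frames`
#'   already carries `segment_id`.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle`: `windows`, `scope`,
#'   `fits_pre`, `fits_post`, `summaries` (all/low/high), `model_pre`,
#'   `model_post`, `model_combined`, `selection`, `peaks`, `log` (record
#'   counts per stage), `config`, `config_hash`.
#' @export
run_pipeline <- function(frames, segments = NULL,
                         config = pipeline_config()) {
  log <- list(n_frames = nrow(frames))
  if (config$standardize) {
    frames$eyebrow_height <- standardize_by_speaker(frames$eyebrow_height,
                                                    frames$speaker)
    frames$pitch <- standardize_by_speaker(frames$pitch, frames$speaker)
  }
  if (!is.null(segments)) {
    frames <- attach_segments(frames, segments)
  }
  log$n_frames_in_segments <- sum(!is.na(frames$segment_id))
  windows <- build_windows(frames, config$half_width)
  log$n_segments <- length(windows)

  scope <- if (length(windows) >= 2L) {
    raise_scope(windows, config$alpha, config$correction)
  } else {
    structure(list(error = "fewer than 2 windows"),
              class = "model_unavailable")
  }

  fits_pre <- sweep_window_sizes(windows, "pre", config$sweep_sizes,
                                 config$fps, config$min_coverage)
  fits_post <- sweep_window_sizes(windows, "post", config$sweep_sizes,
                                  config$fps, config$min_coverage)
  log$n_fits_pre <- sum(!fits_pre$skipped)
  log$n_fits_post <- sum(!fits_post$skipped)

  peaks <- window_peaks(windows)

  split <- split_by_peak(windows, config$peak_split)
  log$n_low_peaks <- length(split$low)
  log$n_high_peaks <- length(split$high)
  summaries <- list(
    eyebrow_all = .safe_model(positional_summary(windows, "eyebrow",
                                                 config$gam_k)),
    pitch_all = .safe_model(positional_summary(windows, "pitch",
                                               config$gam_k)),
    pitch_low = .safe_model(positional_summary(split$low, "pitch",
                                               config$gam_k_split)),
    pitch_high = .safe_model(positional_summary(split$high, "pitch",
                                                config$gam_k_split)))

  sub_fit <- function(fits, size) fits[fits$window_size == size, , drop = FALSE]
  model_pre <- .safe_model(fit_peak_model(
    sub_fit(fits_pre, config$pre_size), peaks, config$predictors_pre))
  model_post <- .safe_model(fit_peak_model(
    sub_fit(fits_post, config$post_size), peaks, config$predictors_post))
  model_combined <- .safe_model(combined_model(
    sub_fit(fits_pre, config$pre_size), sub_fit(fits_post, config$post_size),
    peaks, config$predictors_combined_pre, config$predictors_combined_post))

  selection <- .safe_model({
    models <- lapply(config$sweep_sizes, function(s)
      fit_peak_model(sub_fit(fits_pre, s), peaks, config$predictors_pre))
    names(models) <- config$sweep_sizes
    select_best_window(models)
  })

  structure(list(windows = windows, scope = scope, fits_pre = fits_pre,
                 fits_post = fits_post, summaries = summaries,
                 model_pre = model_pre, model_post = model_post,
                 model_combined = model_combined, selection = selection,
                 peaks = peaks, log = log, config = config,
                 config_hash = .config_hash(config)),
            class = "pipeline_bundle")
}

.mean_r2 <- function(fits, size) {
  r <- fits$r2[fits$window_size == size & !fits$skipped & fits$converged]
  mean(r[is.finite(r)])
}

#' Human-readable pipeline report
#'
#' Formats the three model tables (term, estimate, SE, df, t, p), the scope
#' interval, the window-selection criterion and mean r-squared per region at
#' the reporting sizes. Regenerating from the same bundle yields identical
#' text.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of report lines (also printed invisibly by
#'   `cat`-ing `paste(x, collapse = "\n")`).
#' @export
make_report <- function(bundle) {
  needed <- c("scope", "fits_pre", "fits_post", "model_pre", "model_post",
              "model_combined", "selection", "log", "config")
  missing_parts <- setdiff(needed, names(bundle))
  if (length(missing_parts)) {
    stop("incomplete bundle: missing ", paste(missing_parts, collapse = ", "),
         call. = FALSE)
  }
  cg <- bundle$config
  lines <- c(
    "Audiovisual prosody pipeline report",
    paste0("config hash: ", bundle$config_hash, "  seed: ", cg$seed),
    paste0("segments: ", bundle$log$n_segments,
           "  frames: ", bundle$log$n_frames))
  if (inherits(bundle$scope, "scope_result") &&
      length(bundle$scope$significant_positions)) {
    lines <- c(lines, paste0(
      "raise scope (", bundle$scope$correction, ", alpha ",
      bundle$scope$alpha, "): positions ",
      paste(range(bundle$scope$significant_positions), collapse = " .. ")))
  } else {
    lines <- c(lines, "raise scope: no significant positions")
  }
  fmt_model <- function(m, title) {
    if (inherits(m, "model_unavailable")) {
      return(c(title, paste0("  no model: ", m$error)))
    }
    tab <- m$coefficients
    c(title,
      sprintf("  %-12s %9s %9s %9s %7s %8s", "term", "estimate", "SE",
              "df", "t", "p"),
      sprintf("  %-12s %9.3f %9.3f %9.3f %7.3f %8.3g", tab$term,
              tab$estimate, tab$std_error, tab$df, tab$t_value, tab$p_value))
  }
  ms19 <- 10 * round(window_duration_ms(cg$pre_size, cg$fps) / 10)
  ms17 <- 10 * round(window_duration_ms(cg$post_size, cg$fps) / 10)
  lines <- c(lines,
    fmt_model(bundle$model_pre,
              sprintf("pre-peak model (window %d frames, ~%d ms):",
                      cg$pre_size, ms19)),
    fmt_model(bundle$model_post,
              sprintf("post-peak model (window %d frames, ~%d ms):",
                      cg$post_size, ms17)),
    fmt_model(bundle$model_combined, "combined model:"))
  if (!inherits(bundle$selection, "model_unavailable")) {
    lines <- c(lines,
      paste0("best pre-region window size by AIC: ",
             bundle$selection$window_size),
      paste0("  AIC: ",
             paste(sprintf("%d=%.1f", bundle$selection$criterion$window_size,
                           bundle$selection$criterion$AIC), collapse = " ")))
  } else {
    lines <- c(lines, "window selection: no model")
  }
  r2p <- .mean_r2(bundle$fits_pre, cg$pre_size)
  r2q <- .mean_r2(bundle$fits_post, cg$post_size)
  lines <- c(lines,
    sprintf("mean r2: pre(size %d) = %s  post(size %d) = %s", cg$pre_size,
            formatC(r2p, digits = 3, format = "f"), cg$post_size,
            formatC(r2q, digits = 3, format = "f")))
  lines
}

#' Write the pipeline bundle to disk
#'
#' Serializes the seven analysis artifacts as TSV/text files:
#' `windows.tsv`, `fits_pre.tsv`, `fits_post.tsv`, `scope.tsv`,
#' `summaries.tsv`, `models.tsv`, `selection.tsv`, plus `report.txt`.
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    paths <<- c(paths, p)
  }
  win_long <- do.call(rbind, lapply(bundle$windows, function(w) {
    data.frame(segment_id = w$segment_id, speaker = w$speaker,
               peak_frame = w$peak_frame, peak_height = w$peak_height,
               position = w$positions, eyebrow = w$eyebrow, pitch = w$pitch,
               stringsAsFactors = FALSE)
  }))
  wt(win_long, "windows.tsv")
  wt(bundle$fits_pre, "fits_pre.tsv")
  wt(bundle$fits_post, "fits_post.tsv")
  if (inherits(bundle$scope, "scope_result")) {
    wt(data.frame(position = as.integer(names(bundle$scope$p_values)),
                  p_adjusted = unname(bundle$scope$p_values),
                  significant = as.integer(names(bundle$scope$p_values)) %in%
                    bundle$scope$significant_positions),
       "scope.tsv")
  } else {
    wt(data.frame(position = integer(), p_adjusted = numeric(),
                  significant = logical()), "scope.tsv")
  }
  summ <- do.call(rbind, lapply(names(bundle$summaries), function(nm) {
    s <- bundle$summaries[[nm]]
    if (inherits(s, "model_unavailable")) return(NULL)
    data.frame(subset = nm, position = s$position, mean = s$mean,
               lo = s$lo, hi = s$hi, stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) summ <- data.frame(subset = character(),
                                        position = integer(),
                                        mean = numeric(), lo = numeric(),
                                        hi = numeric())
  wt(summ, "summaries.tsv")
  mods <- do.call(rbind, lapply(
    list(pre = bundle$model_pre, post = bundle$model_post,
         combined = bundle$model_combined), function(m) {
      if (inherits(m, "model_unavailable")) return(NULL)
      cbind(model = m$region, m$coefficients)
    }))
  if (is.null(mods)) mods <- data.frame(model = character(),
                                        term = character())
  wt(mods, "models.tsv")
  sel <- if (inherits(bundle$selection, "model_unavailable")) {
    data.frame(window_size = integer(), AIC = numeric())
  } else bundle$selection$criterion
  wt(sel, "selection.tsv")
  rp <- file.path(dir, "report.txt")
  writeLines(make_report(bundle), rp)
  paths <- c(paths, rp)
  invisible(paths)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(paste(make_report(x), collapse = "\n"), "\n")
  invisible(x)
}
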