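# Refits of the original study's published measurement files. The files are
# not shipped with the package; point `supplementary_dir` at a directory
# holding df_sample.tsv, df_sample_pitch.tsv, df_sample_eb.tsv (and
# optionally res_df_nls_pre.tsv / res_df_nls_post.tsv).

#' Duration of an n-frame window in milliseconds
#'
#' @param n_frames Number of frames in the window.
#' @param fps Frames per second (default 30).
#' @return Duration in milliseconds (`n_frames / fps * 1000`).
#' @export
window_duration_ms <- function(n_frames, fps = 30) {
  stopifnot(fps > 0)
  n_frames / fps * 1000
}

#' Locate the supplementary-data directory
#'
#' Checks, in order: the `dir` argument, the option
#' `avprosody.supplementary_dir`, the environment variable
#' `AVPROSODY_SUPPLEMENTARY`. Returns `NULL` when none points at an
#' existing directory.
#'
#' @param dir Optional explicit path.
#' @return A path or `NULL`.
#' @export
supplementary_dir <- function(dir = NULL) {
  cands <- c(dir, getOption("avprosody.supplementary_dir"),
             Sys.getenv("AVPROSODY_SUPPLEMENTARY", ""))
  cands <- cands[nzchar(cands)]
  for (d in cands) if (dir.exists(d)) return(d)
  NULL
}

.supp_windows <- function(dir, speakers = NULL) {
  pitch <- read_window_table(file.path(dir, "df_sample_pitch.tsv"))
  eb_path <- file.path(dir, "df_sample_eb.tsv")
  eb <- if (file.exists(eb_path)) read_window_table(eb_path) else NULL
  lapply(stats::setNames(names(pitch), names(pitch)), function(id) {
    ebv <- if (!is.null(eb) && id %in% names(eb)) eb[[id]]
           else rep(NA_real_, 121L)
    sp <- if (!is.null(speakers) && id %in% names(speakers)) speakers[[id]]
          else sub("-.*$", "", id)
    structure(list(segment_id = id, speaker = sp, peak_frame = NA_integer_,
                   peak_height = ebv[61L], positions = -60:60,
                   eyebrow = ebv, pitch = pitch[[id]]),
              class = "segment_window")
  })
}

#' Refit the published worked-example segments
#'
#' Fits the post-peak sinusoid (window 17 frames) to segments `0099-0249`
#' and `0099-0337` of the published pitch-window file and returns their
#' amplitude, frequency and phase at printed precision alongside the raw
#' estimates.
#'
#' @param dir Supplementary-data directory (see [supplementary_dir()]).
#' @return A `data.frame` with one row per segment: `segment_id`, `A`, `f`,
#'   `phi`, `phase`, `r2`.
#' @export
reproduce_worked_examples <- function(dir = supplementary_dir()) {
  if (is.null(dir)) {
    stop("supplementary data not available; set ",
         "options(avprosody.supplementary_dir = ...)", call. = FALSE)
  }
  windows <- .supp_windows(dir)
  ids <- c("0099-0249", "0099-0337")
  missing_ids <- setdiff(ids, names(windows))
  if (length(missing_ids)) {
    stop("segment(s) not found in df_sample_pitch.tsv: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    fit <- fit_region(windows[[id]], "post", 17L)
    if (inherits(fit, "sine_skip")) {
      stop("worked-example fit skipped: ", fit$reason, call. = FALSE)
    }
    p <- fit$params
    data.frame(segment_id = id, A = p$A, f = p$f, phi = p$phi,
               phase = phase_category(p$phi), r2 = fit$r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Refit the published mixed-model tables
#'
#' Recomputes, from the published window files, the separate pre-peak
#' (window 19) and post-peak (window 17) mixed models, the combined model,
#' the mean r-squared at window size 20, and the segment count.
#'
#' @param dir Supplementary-data directory.
#' @param speakers Optional named character vector mapping segment ids to
#'   speakers; by default the episode prefix of the segment id is used as
#'   the grouping factor.
#' @return A list with `model_pre`, `model_post`, `model_combined`
#'   (`peak_model` objects), `mean_r2_20`, `n_segments`.
#' @export
reproduce_table_models <- function(dir = supplementary_dir(),
                                   speakers = NULL) {
  if (is.null(dir)) {
    stop("supplementary data not available; set ",
         "options(avprosody.supplementary_dir = ...)", call. = FALSE)
  }
  windows <- .supp_windows(dir, speakers)
  peaks <- data.frame(
    segment_id = names(windows),
    speaker = vapply(windows, `[[`, character(1L), "speaker"),
    peak_height = vapply(windows, `[[`, numeric(1L), "peak_height"),
    stringsAsFactors = FALSE)
  pre19 <- fit_table(windows, "pre", 19L)
  post17 <- fit_table(windows, "post", 17L)
  pre20 <- fit_table(windows, "pre", 20L)
  post20 <- fit_table(windows, "post", 20L)
  r2 <- c(pre20$r2[!pre20$skipped & pre20$converged],
          post20$r2[!post20$skipped & post20$converged])
  list(model_pre = fit_peak_model(pre19, peaks, c("A", "f", "phi")),
       model_post = fit_peak_model(post17, peaks, c("A", "f")),
       model_combined = combined_model(pre19, post17, peaks),
       mean_r2_20 = mean(r2[is.finite(r2)]),
       n_segments = length(windows))
}
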