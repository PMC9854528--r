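# Segment windows: 121 positions (-60..+60) centered on the segment's
# eyebrow peak; truncation beyond the segment is represented as NA.

#' Attach subtitle segments to frame records
#'
#' Assigns each frame falling in a segment's half-open interval
#' `[start_frame, end_frame)` that segment's id; frames outside every
#' segment keep `NA`. Segments of one episode must not overlap.
#'
#' @param records Frame table (see [read_frame_table()]).
#' @param segments Segment table (see [parse_srt()]).
#' @return The frame table with `segment_id` filled in.
#' @export
attach_segments <- function(records, segments) {
  records$segment_id <- NA_character_
  for (ep in unique(segments$episode)) {
    seg <- segments[segments$episode == ep, , drop = FALSE]
    seg <- seg[order(seg$start_frame), , drop = FALSE]
    if (nrow(seg) > 1L) {
      ov <- which(seg$start_frame[-1L] < seg$end_frame[-nrow(seg)])
      if (length(ov)) {
        stop("overlapping segments in episode ", ep, ": ",
             seg$segment_id[ov[1L]], " and ", seg$segment_id[ov[1L] + 1L],
             call. = FALSE)
      }
    }
    rsel <- which(records$episode == ep)
    if (!length(rsel)) next
    fr <- records$frame[rsel]
    # findInterval over sorted starts; then check frame < end of that segment
    k <- findInterval(fr, seg$start_frame)
    hit <- k >= 1L & fr < seg$end_frame[pmax(k, 1L)]
    records$segment_id[rsel[hit]] <- seg$segment_id[k[hit]]
  }
  records
}

#' Locate the eyebrow peak of a segment
#'
#' The frame with maximal (standardized) eyebrow height; ties are broken to
#' the earliest frame so results do not depend on row order.
#'
#' @param segment_records Frame rows of one segment.
#' @return A list with `peak_frame` and `peak_height`.
#' @export
find_eyebrow_peak <- function(segment_records) {
  o <- order(segment_records$frame)
  eb <- segment_records$eyebrow_height[o]
  fr <- segment_records$frame[o]
  if (all(is.na(eb))) {
    stop("no non-missing eyebrow values in segment", call. = FALSE)
  }
  i <- which.max(eb)  # NA never wins; ties -> first (earliest frame)
  list(peak_frame = fr[i], peak_height = eb[i])
}

#' Extract the analysis window around an eyebrow peak
#'
#' Copies eyebrow and pitch values to positions `-half_width ... +half_width`
#' relative to the peak. Positions before the segment start or after its end
#' are `NA` ("up to 60 measurements" on either side); position 0 always holds
#' the segment's maximal eyebrow value.
#'
#' @param segment_records Frame rows of one segment (one speaker).
#' @param peak_frame Frame index of the eyebrow peak.
#' @param half_width Window half-width in frames (default 60).
#' @return An object of class `segment_window`: a list with `segment_id`,
#'   `speaker`, `peak_frame`, `peak_height`, `positions`, `eyebrow`, `pitch`.
#' @export
extract_window <- function(segment_records, peak_frame, half_width = 60L) {
  o <- order(segment_records$frame)
  sr <- segment_records[o, , drop = FALSE]
  if (!peak_frame %in% sr$frame) {
    stop("peak_frame is not inside the segment", call. = FALSE)
  }
  positions <- seq.int(-half_width, half_width)
  want <- peak_frame + positions
  idx <- match(want, sr$frame)
  eb <- ifelse(is.na(idx), NA_real_, sr$eyebrow_height[idx])
  pi_ <- ifelse(is.na(idx), NA_real_, sr$pitch[idx])
  structure(list(
    segment_id = sr$segment_id[1L],
    speaker = sr$speaker[1L],
    peak_frame = peak_frame,
    peak_height = sr$eyebrow_height[match(peak_frame, sr$frame)],
    positions = positions,
    eyebrow = as.numeric(eb),
    pitch = as.numeric(pi_)
  ), class = "segment_window")
}

#' @export
print.segment_window <- function(x, ...) {
  cat("Segment window", x$segment_id, "(speaker", paste0(x$speaker, ")"),
      "\n  peak frame:", x$peak_frame,
      " peak height:", format(x$peak_height, digits = 4),
      "\n  pitch coverage:", sum(!is.na(x$pitch)), "/", length(x$pitch),
      "positions\n")
  invisible(x)
}

#' Build all segment windows of a frame table
#'
#' Runs [find_eyebrow_peak()] and [extract_window()] per segment. Segments
#' without any non-missing eyebrow value are dropped with a message.
#'
#' @param records Frame table with `segment_id` assigned (see
#'   [attach_segments()]).
#' @param half_width Window half-width in frames (default 60).
#' @return A named list of `segment_window` objects keyed by segment id.
#' @export
build_windows <- function(records, half_width = 60L) {
  recs <- records[!is.na(records$segment_id), , drop = FALSE]
  ids <- unique(recs$segment_id)
  out <- vector("list", length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    sr <- recs[recs$segment_id == ids[i], , drop = FALSE]
    if (all(is.na(sr$eyebrow_height))) next
    pk <- find_eyebrow_peak(sr)
    out[[i]] <- extract_window(sr, pk$peak_frame, half_width)
    keep[i] <- TRUE
  }
  if (any(!keep)) {
    message(sum(!keep), " segment(s) dropped: no non-missing eyebrow values")
  }
  out <- out[keep]
  names(out) <- ids[keep]
  out
}

#' Peak-height table of a window collection
#'
#' @param windows List of `segment_window` objects.
#' @return A `data.frame` with `segment_id`, `speaker`, `peak_height` —
#'   the response table consumed by [fit_peak_model()] and
#'   [combined_model()].
#' @export
window_peaks <- function(windows) {
  out <- data.frame(
    segment_id = vapply(windows, `[[`, character(1L), "segment_id"),
    speaker = vapply(windows, `[[`, character(1L), "speaker"),
    peak_height = vapply(windows, `[[`, numeric(1L), "peak_height"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fill missing values by linear interpolation
#'
#' Interior `NA` runs are linearly interpolated between the nearest
#' non-missing neighbors; leading and trailing runs are filled by nearest
#' value extension (a single observed value extends to the whole vector).
#' Non-missing values are never changed.
#'
#' @param values Numeric vector with at least one non-missing entry.
#' @return Numeric vector without `NA`.
#' @export
interpolate_missing <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) {
    stop("need at least 1 non-missing value to interpolate", call. = FALSE)
  }
  if (all(ok)) return(values)
  if (sum(ok) == 1L) return(rep(values[ok], length(values)))
  idx <- seq_along(values)
  stats::approx(idx[ok], values[ok], xout = idx, method = "linear",
                rule = 2)$y
}

#' Positional scope of the brow raise
#'
#' For every window position, a Mann-Whitney U test compares the eyebrow
#' heights observed at that position against the pooled heights over all
#' positions, with multiplicity correction across positions. The default
#' alternative is `"greater"` — a position belongs to the raise scope when
#' its heights are significantly *higher* than the pooled distribution —
#' and the contiguous run of significant positions around 0 estimates the
#' temporal scope of the raise.
#'
#' @param windows List of `segment_window` objects.
#' @param alpha Significance level after correction (default 0.05).
#' @param correction Method passed to [stats::p.adjust()] (default
#'   `"holm"`).
#' @param signal `"eyebrow"` (default) or `"pitch"`.
#' @param alternative Test direction (default `"greater"`).
#' @return An object of class `scope_result` with elements `p_values`
#'   (named by position), `significant_positions`, `alpha`, `correction`.
#' @export
raise_scope <- function(windows, alpha = 0.05, correction = "holm",
                        signal = c("eyebrow", "pitch"),
                        alternative = c("greater", "two.sided", "less")) {
  signal <- match.arg(signal)
  alternative <- match.arg(alternative)
  if (length(windows) < 2L) {
    stop("need at least 2 windows for the scope test", call. = FALSE)
  }
  mat <- vapply(windows, function(w) w[[signal]],
                numeric(length(windows[[1L]]$positions)))
  positions <- windows[[1L]]$positions
  pooled <- as.vector(mat)
  pooled <- pooled[!is.na(pooled)]
  pv <- rep(NA_real_, length(positions))
  for (i in seq_along(positions)) {
    x <- mat[i, ]
    x <- x[!is.na(x)]
    if (length(x) < 2L) next
    pv[i] <- suppressWarnings(
      stats::wilcox.test(x, pooled, alternative = alternative,
                         exact = FALSE)$p.value)
  }
  adj <- stats::p.adjust(pv, method = correction)
  sig <- positions[!is.na(adj) & adj < alpha]
  structure(list(p_values = stats::setNames(adj, positions),
                 raw_p_values = stats::setNames(pv, positions),
                 significant_positions = sig,
                 alpha = alpha, correction = correction, signal = signal,
                 n_windows = length(windows)),
            class = "scope_result")
}

#' @export
print.scope_result <- function(x, ...) {
  cat("Positional scope test (", x$signal, ", Mann-Whitney vs pooled, ",
      x$correction, " correction, alpha = ", x$alpha, ")\n", sep = "")
  if (length(x$significant_positions)) {
    cat("  significant positions:",
        paste(range(x$significant_positions), collapse = " .. "),
        sprintf("(%d positions)\n", length(x$significant_positions)))
  } else {
    cat("  no significant positions\n")
  }
  invisible(x)
}
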