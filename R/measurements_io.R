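# Canonical frame-table schema. Pitch is NA on voiceless/undetected frames;
# "NA" is the on-disk missing token.
.frame_cols <- c("speaker", "episode", "segment_id", "frame",
                 "eyebrow_height", "lat_angle", "sag_angle", "pitch")
.frame_numeric <- c("frame", "eyebrow_height", "lat_angle", "sag_angle", "pitch")

#' Read a frame-level measurement table
#'
#' Reads a tab-separated table with one row per video frame (30 fps
#' convention) holding speaker, episode, segment id, frame index, eyebrow
#' height, lateral and sagittal head angles, and pitch. Pitch cells that are
#' empty or unparseable become `NA` (voiceless frames). Rows are returned
#' sorted by (speaker, episode, frame).
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(pitch = "F0", eyebrow_height = "eb")`. Lets foreign tables load
#'   without renaming on disk.
#' @return A `data.frame` with columns `speaker`, `episode`, `segment_id`,
#'   `frame`, `eyebrow_height`, `lat_angle`, `sag_angle`, `pitch`.
#' @seealso [write_frame_table()]
#' @export
read_frame_table <- function(path, column_map = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("column_map must be a fully named character vector ",
           "(canonical name -> file column name)", call. = FALSE)
    }
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column_map refers to absent file column: ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(.frame_cols, names(df))
  # segment_id is permitted to be absent (assigned later from subtitles)
  missing_cols <- setdiff(missing_cols, "segment_id")
  if (length(missing_cols)) {
    stop("frame table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"segment_id" %in% names(df)) df$segment_id <- NA_character_
  df <- df[, .frame_cols]
  for (col in .frame_numeric) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$segment_id[df$segment_id %in% c("", "NA")] <- NA_character_
  df$frame <- as.integer(df$frame)
  if (anyNA(df$frame)) stop("non-integer frame index in frame table", call. = FALSE)
  key <- paste(df$episode, df$frame, df$speaker, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (episode, frame, speaker) record: ",
         gsub("\r", "/", dup), call. = FALSE)
  }
  df <- df[order(df$speaker, df$episode, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a frame-level measurement table
#'
#' Writes the canonical TSV layout (fixed column order, tab separated, header
#' row, missing pitch as the literal token `NA`). `read_frame_table()` on the
#' result reproduces the input.
#'
#' @param records Frame table as returned by [read_frame_table()] or
#'   [generate_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_frame_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot write an empty frame table", call. = FALSE)
  }
  missing_cols <- setdiff(.frame_cols, names(records))
  if (length(missing_cols)) {
    stop("frame table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.table(records[, .frame_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.parse_srt_time <- function(s, lineno) {
  m <- regmatches(s, regexec("^(\\d{2}):(\\d{2}):(\\d{2}),(\\d{3})$", s))[[1L]]
  if (length(m) != 5L) {
    stop("malformed SRT timestamp at line ", lineno, ": '", s, "'",
         call. = FALSE)
  }
  v <- as.numeric(m[2:5])
  v[1L] * 3600 + v[2L] * 60 + v[3L] + v[4L] / 1000
}

#' Parse a SubRip subtitle file into frame-indexed segments
#'
#' Converts SubRip cue times to half-open frame intervals
#' `[floor(start * fps), floor(end * fps))` so adjacent subtitles never share
#' a frame. Segment ids follow the `<episode>-<index>` convention with the
#' subtitle index zero-padded to 4 digits (e.g. segment 2372 of `0145.srt`
#' becomes `"0145-2372"`).
#'
#' @param path Path to a `.srt` file.
#' @param fps Frames per second of the associated video (default 30).
#' @param episode Episode identifier; defaults to the file name without
#'   extension.
#' @return A `data.frame` with columns `segment_id`, `episode`, `start_frame`,
#'   `end_frame`, `text`. Empty files yield zero rows.
#' @export
parse_srt <- function(path, fps = 30, episode = NULL) {
  stopifnot(fps > 0)
  if (is.null(episode)) {
    episode <- sub("\\.[sS][rR][tT]$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines, fixed = TRUE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    idx <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(idx)) stop("expected subtitle index at line ", i, call. = FALSE)
    i <- i + 1L
    if (i > n) stop("truncated subtitle block at line ", i, call. = FALSE)
    tl <- trimws(lines[i])
    parts <- strsplit(tl, "\\s+-->\\s+")[[1L]]
    if (length(parts) != 2L) {
      stop("malformed SRT timestamp at line ", i, ": '", tl, "'", call. = FALSE)
    }
    t0 <- .parse_srt_time(parts[1L], i)
    t1 <- .parse_srt_time(parts[2L], i)
    i <- i + 1L
    txt <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      txt <- c(txt, lines[i])
      i <- i + 1L
    }
    # tiny epsilon guards against binary representation of decimal times
    start_frame <- floor(t0 * fps + 1e-6)
    end_frame <- floor(t1 * fps + 1e-6)
    if (end_frame <= start_frame) {
      stop("invalid subtitle interval (end <= start) for index ", idx,
           call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      segment_id = sprintf("%s-%04d", episode, idx),
      episode = episode,
      start_frame = as.integer(start_frame),
      end_frame = as.integer(end_frame),
      text = paste(txt, collapse = "\n"),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(segment_id = character(), episode = character(),
                      start_frame = integer(), end_frame = integer(),
                      text = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  if (anyDuplicated(res$segment_id)) {
    stop("duplicate segment ids in ", path, call. = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write segments to a SubRip subtitle file
#'
#' Inverse of [parse_srt()] up to frame quantization: frame intervals are
#' converted back to timestamps at `frame / fps` seconds.
#'
#' @param segments Segment table with `segment_id`, `start_frame`,
#'   `end_frame` and optionally `text`.
#' @param path Output path.
#' @param fps Frames per second (default 30).
#' @return Invisibly, `path`.
#' @export
write_srt <- function(segments, path, fps = 30) {
  fmt_time <- function(f) {
    # round sub-millisecond remainders up so floor(t * fps) recovers the
    # frame index exactly on re-parse
    ms <- ceiling(f / fps * 1000 - 1e-9)
    h <- ms %/% 3600000; ms <- ms - h * 3600000
    mn <- ms %/% 60000; ms <- ms - mn * 60000
    s <- ms %/% 1000; ms <- ms - s * 1000
    sprintf("%02d:%02d:%02d,%03d", h, mn, s, ms)
  }
  idx <- as.integer(sub("^.*-", "", segments$segment_id))
  txt <- if ("text" %in% names(segments)) segments$text else rep("", nrow(segments))
  blocks <- vapply(seq_len(nrow(segments)), function(i) {
    paste0(idx[i], "\n",
           fmt_time(segments$start_frame[i]), " --> ",
           fmt_time(segments$end_frame[i]), "\n",
           txt[i], "\n")
  }, character(1L))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

.window_positions <- -60:60

#' Read a table of 121-position analysis windows
#'
#' Each series spans positions -60..+60 around a segment's eyebrow peak.
#' Two layouts are supported: `"wide"` (one row per segment; a `segment_id`
#' column followed by 121 position columns named `-60` ... `60`) and `"long"`
#' (`segment_id`, `position`, `value` rows). Positions absent from the file
#' are `NA`.
#'
#' @param path Path to a TSV file.
#' @param orientation `"wide"`, `"long"`, or `"auto"` (detect from the
#'   header).
#' @return A named list of numeric vectors of length 121 (names are segment
#'   ids; vector names are positions `-60` ... `60`).
#' @seealso [write_window_table()]
#' @export
read_window_table <- function(path, orientation = c("auto", "wide", "long")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  if (orientation == "auto") {
    orientation <- if (all(c("position", "value") %in% names(df))) "long"
      else if (any(names(df) %in% as.character(.window_positions))) "wide"
      else stop("cannot detect window-table orientation from header: ",
                paste(utils::head(names(df), 5), collapse = ", "),
                call. = FALSE)
  }
  empty <- stats::setNames(rep(NA_real_, 121L), as.character(.window_positions))
  if (orientation == "long") {
    stopifnot(all(c("segment_id", "position", "value") %in% names(df)))
    if (any(df$position < -60 | df$position > 60)) {
      stop("window position outside [-60, 60]", call. = FALSE)
    }
    ids <- unique(df$segment_id)
    out <- lapply(ids, function(id) {
      sub <- df[df$segment_id == id, ]
      s <- empty
      s[as.character(sub$position)] <- sub$value
      s
    })
    names(out) <- ids
    return(out)
  }
  pos_cols <- intersect(names(df), as.character(.window_positions))
  bad <- setdiff(names(df), c("segment_id", as.character(.window_positions)))
  if (length(bad)) {
    badnum <- suppressWarnings(as.numeric(bad))
    if (any(!is.na(badnum))) {
      stop("window position outside [-60, 60]: ",
           paste(bad[!is.na(badnum)], collapse = ", "), call. = FALSE)
    }
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    s <- empty
    s[pos_cols] <- as.numeric(df[i, pos_cols])
    s
  })
  names(out) <- df$segment_id
  out
}

#' Write a table of 121-position analysis windows
#'
#' @param series Named list of numeric vectors of length 121 (positions
#'   -60..60), as returned by [read_window_table()].
#' @param path Output path.
#' @param orientation `"wide"` (default) or `"long"`. Long output drops `NA`
#'   cells; wide output writes them as `NA`.
#' @return Invisibly, `path`.
#' @export
write_window_table <- function(series, path, orientation = c("wide", "long")) {
  orientation <- match.arg(orientation)
  stopifnot(length(series) > 0L, !is.null(names(series)))
  for (s in series) {
    if (length(s) != 121L) stop("each series must have 121 positions", call. = FALSE)
  }
  if (orientation == "wide") {
    mat <- do.call(rbind, series)
    df <- data.frame(segment_id = names(series), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("segment_id", as.character(.window_positions))
  } else {
    df <- do.call(rbind, lapply(names(series), function(id) {
      v <- series[[id]]
      keep <- !is.na(v)
      data.frame(segment_id = id, position = .window_positions[keep],
                 value = unname(v[keep]), stringsAsFactors = FALSE)
    }))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
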