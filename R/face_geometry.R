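# Landmark indices follow the standard 68-point annotation, 0-based.
# Coordinate convention: x right, y up, z toward the camera (right-handed).

#' Configuration for landmark-based face measurements
#'
#' Defaults follow the standard 68-point annotation (0-based): the ten brow
#' landmarks 17-26, four landmarks delimiting the nose
#' (bridge top 27, wing extremes 31 and 35, tip base 33), and the outer eye
#' corners 36/45 as the normalizing distance. All three sets are
#' configurable; per-speaker standardization downstream makes the analysis
#' insensitive to the normalizer choice.
#'
#' @param brow_indices Ten 0-based indices marking the eyebrows.
#' @param nose_indices Four 0-based indices delimiting the nose.
#' @param scale_indices Pair of 0-based indices whose distance normalizes the
#'   brow-nose distance.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(brow_indices = 17:26,
                            nose_indices = c(27L, 31L, 33L, 35L),
                            scale_indices = c(36L, 45L)) {
  brow_indices <- as.integer(brow_indices)
  nose_indices <- as.integer(nose_indices)
  scale_indices <- as.integer(scale_indices)
  stopifnot(length(brow_indices) == 10L, length(nose_indices) == 4L,
            length(scale_indices) == 2L)
  all_idx <- c(brow_indices, nose_indices)
  if (any(all_idx < 0L | all_idx > 67L) ||
      any(scale_indices < 0L | scale_indices > 67L)) {
    stop("landmark indices must lie in 0..67", call. = FALSE)
  }
  if (length(intersect(brow_indices, nose_indices))) {
    stop("brow and nose index sets must be disjoint", call. = FALSE)
  }
  structure(list(brow_indices = brow_indices, nose_indices = nose_indices,
                 scale_indices = scale_indices),
            class = "geometry_config")
}

.check_landmarks <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 3L) {
    stop("landmark set must be a 68 x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  points
}

#' Eyebrow height as a normalized brow-nose distance
#'
#' The distance between the centroid of the ten brow landmarks and the
#' centroid of the four nose landmarks, divided by the distance between the
#' two scale landmarks (outer eye corners by default). The ratio is invariant
#' under rigid motion and uniform scaling of the landmark set, so it tracks
#' brow raises rather than face size or camera distance.
#'
#' @param landmarks A 68 x 3 numeric matrix of (x, y, z) coordinates.
#' @param config A [geometry_config()].
#' @return A positive scalar.
#' @export
eyebrow_height_ratio <- function(landmarks, config = geometry_config()) {
  p <- .check_landmarks(landmarks)
  brow_c <- colMeans(p[config$brow_indices + 1L, , drop = FALSE])
  nose_c <- colMeans(p[config$nose_indices + 1L, , drop = FALSE])
  scale_d <- sqrt(sum((p[config$scale_indices[1L] + 1L, ] -
                       p[config$scale_indices[2L] + 1L, ])^2))
  if (scale_d <= .Machine$double.eps) {
    stop("degenerate face: zero normalizing distance", call. = FALSE)
  }
  sqrt(sum((brow_c - nose_c)^2)) / scale_d
}

#' Lateral and sagittal head angles from 3D landmarks
#'
#' Lateral angle: signed rotation (degrees) of the inter-ocular axis (outer
#' eye corner 36 to 45) about the camera's depth axis; positive when the
#' right eye is higher. Sagittal angle: signed elevation (degrees) of the
#' nose-bridge vector (tip 30 to bridge top 27) out of the frontal plane;
#' positive when the head tilts up. A frontal, symmetric face gives (0, 0).
#'
#' @param landmarks A 68 x 3 numeric matrix (x right, y up, z toward camera).
#' @return Named numeric vector `c(lateral = ..., sagittal = ...)` in
#'   degrees.
#' @export
head_angles <- function(landmarks) {
  p <- .check_landmarks(landmarks)
  ocular <- p[46L, ] - p[37L, ]           # landmarks 45 and 36 (0-based)
  if (sqrt(sum(ocular[1:2]^2)) <= .Machine$double.eps) {
    stop("degenerate geometry: eye corners coincide in the image plane",
         call. = FALSE)
  }
  lateral <- atan2(ocular[2L], ocular[1L]) * 180 / pi
  bridge <- p[28L, ] - p[31L, ]           # landmarks 27 and 30 (0-based)
  nb <- sqrt(sum(bridge^2))
  if (nb <= .Machine$double.eps) {
    stop("degenerate geometry: nose-bridge landmarks coincide", call. = FALSE)
  }
  sagittal <- asin(pmin(1, pmax(-1, bridge[3L] / nb))) * 180 / pi
  c(lateral = unname(lateral), sagittal = unname(sagittal))
}

#' Standardize measurements within speakers
#'
#' Centers and scales `values` to mean 0, sample SD 1 within each speaker
#' group. `NA` values pass through unchanged and are excluded from the
#' moments, so voiceless pitch frames do not distort the scaling.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param speaker Grouping vector of the same length.
#' @return Numeric vector of z-scores, `NA` where `values` was `NA`.
#' @export
standardize_by_speaker <- function(values, speaker) {
  stopifnot(length(values) == length(speaker))
  out <- rep(NA_real_, length(values))
  for (sp in unique(speaker)) {
    sel <- speaker == sp
    v <- values[sel]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      stop("speaker '", sp, "' has fewer than 2 non-missing values",
           call. = FALSE)
    }
    s <- stats::sd(v[ok])
    if (s <= .Machine$double.eps) {
      stop("zero variance for speaker '", sp, "': cannot standardize",
           call. = FALSE)
    }
    out[sel] <- (v - mean(v[ok])) / s
  }
  out
}

#' A symmetric frontal 68-point face template
#'
#' A synthetic, perfectly symmetric landmark set in canonical pose
#' (x right, y up, z toward the camera), used for geometry testing and as a
#' seed for rotated examples. It is not derived from any real face.
#'
#' @return A 68 x 3 numeric matrix.
#' @export
frontal_face_template <- function() {
  p <- matrix(0, 68L, 3L)
  # jaw 0-16: ellipse arc
  th <- seq(pi, 2 * pi, length.out = 17L)
  p[1:17, 1L] <- 8 * cos(th)
  p[1:17, 2L] <- 10 * sin(th) - 2
  # brows 17-26: two arcs, symmetric
  xs <- seq(-6, -1.5, length.out = 5L)
  p[18:22, 1L] <- xs
  p[18:22, 2L] <- 5 + 0.5 * cos(seq(-1, 1, length.out = 5L))
  p[23:27, 1L] <- -rev(xs)
  p[23:27, 2L] <- rev(p[18:22, 2L])
  # nose bridge 27-30 (vertical), base 31-35
  p[28:31, 1L] <- 0
  p[28:31, 2L] <- seq(3, 0, length.out = 4L)
  p[28:31, 3L] <- 0.5   # constant depth: canonical pose has the bridge in the frontal plane
  p[32:36, 1L] <- seq(-1.5, 1.5, length.out = 5L)
  p[32:36, 2L] <- -1
  p[32:36, 3L] <- c(1, 1.4, 1.6, 1.4, 1)
  # eyes 36-41 (right of viewer: speaker's right eye at negative x), 42-47
  eye <- function(cx) cbind(cx + c(-1.2, -0.6, 0.6, 1.2, 0.6, -0.6),
                            c(3, 3.4, 3.4, 3, 2.6, 2.6), 0.3)
  p[37:42, ] <- eye(-3.5)
  p[43:48, ] <- eye(3.5)
  # mouth 48-67: two ellipses
  th2 <- seq(0, 2 * pi, length.out = 13L)[-13L]
  p[49:60, 1L] <- 2.5 * cos(th2)
  p[49:60, 2L] <- -4 + 1.2 * sin(th2)
  th3 <- seq(0, 2 * pi, length.out = 9L)[-9L]
  p[61:68, 1L] <- 1.5 * cos(th3)
  p[61:68, 2L] <- -4 + 0.6 * sin(th3)
  p
}

#' Read a landmark coordinate table
#'
#' Expects a TSV with columns `frame`, `speaker`, then `x0, y0, z0, ...,
#' x67, y67, z67` (204 coordinate columns).
#'
#' @param path Path to the TSV file.
#' @return A list with `meta` (data.frame of frame, speaker) and `coords`
#'   (list of 68 x 3 matrices, one per row).
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  want <- as.vector(t(outer(0:67, c("x", "y", "z"),
                            function(i, a) paste0(a, i))))
  missing_cols <- setdiff(c("frame", "speaker", want), names(df))
  if (length(missing_cols)) {
    stop("landmark table is missing column(s): ",
         paste(utils::head(missing_cols, 6), collapse = ", "), call. = FALSE)
  }
  coords <- lapply(seq_len(nrow(df)), function(i) {
    matrix(as.numeric(df[i, want]), ncol = 3L, byrow = TRUE)
  })
  list(meta = df[, c("frame", "speaker")], coords = coords)
}

#' Compute frame measurements from landmark sets
#'
#' Applies [eyebrow_height_ratio()] and [head_angles()] to each landmark set
#' and assembles a frame table (pitch left `NA`; it comes from the acoustic
#' pipeline, not from landmarks).
#'
#' @param landmark_data A list as returned by [read_landmark_table()].
#' @param config A [geometry_config()].
#' @param episode Episode identifier for the output rows.
#' @return A frame-table `data.frame` (see [read_frame_table()]).
#' @export
compute_face_measurements <- function(landmark_data,
                                      config = geometry_config(),
                                      episode = "0000") {
  meta <- landmark_data$meta
  n <- nrow(meta)
  eb <- numeric(n); lat <- numeric(n); sag <- numeric(n)
  for (i in seq_len(n)) {
    p <- landmark_data$coords[[i]]
    eb[i] <- eyebrow_height_ratio(p, config)
    a <- head_angles(p)
    lat[i] <- a[["lateral"]]; sag[i] <- a[["sagittal"]]
  }
  data.frame(speaker = meta$speaker, episode = episode,
             segment_id = NA_character_, frame = as.integer(meta$frame),
             eyebrow_height = eb, lat_angle = lat, sag_angle = sag,
             pitch = NA_real_, stringsAsFactors = FALSE)
}
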