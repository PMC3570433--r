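# Block-matching speckle tracking: the weighted sum-of-squared-differences
# criterion
#
#   eps(dx, dy) = sum_y sum_x [I(x, y, t) - I(x + dx, y + dy, t + 1)]^2 w(x, y)
#
# minimised over integer shifts.  w is a per-pixel weighting (all ones in
# the simplest case).  Matching is integer-pixel; optional parabolic
# sub-pixel refinement of the eps surface around the minimum is available
# behind a flag so that the core criterion stays the plain integer SSD.

#' Define a rectangular region of interest
#'
#' @param x0,y0 Top-left pixel (0-based column / row).
#' @param width,height Extent in pixels (half-open; >= 1).
#' @param label Region name.
#' @return Object of class `"roi"`.
#' @export
roi <- function(x0, y0, width, height, label = "roi") {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("ROI must be at least 1x1",
                                      call. = FALSE)
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 label = as.character(label)),
            class = "roi")
}

.roi_in_frame <- function(r, shape)
  r$x0 >= 0L && r$y0 >= 0L && r$x0 + r$width <= shape[2] &&
    r$y0 + r$height <= shape[1]

# extract the ROI block (1-based matrix indexing from 0-based coordinates)
.roi_block <- function(frame, r)
  frame[r$y0 + seq_len(r$height), r$x0 + seq_len(r$width), drop = FALSE]

#' Match one ROI between two frames
#'
#' Exhaustively evaluates the weighted squared-difference criterion over
#' every integer shift in `[-radius, radius]^2` that keeps the shifted
#' block inside `frame_t1`, and returns the global minimiser.  Ties are
#' broken by the smallest Euclidean shift length, then lexicographically by
#' (dy, dx).
#'
#' @param frame_t,frame_t1 Numeric H x W matrices (consecutive frames).
#' @param r An [roi()] positioned inside `frame_t`.
#' @param radius Search radius in pixels (>= 0).
#' @param weight `NULL` for uniform weighting, or a height x width matrix
#'   of non-negative pixel weights.
#' @param subpixel If `TRUE`, additionally report `dx_sub`, `dy_sub`: a
#'   parabolic fit of the error surface around the integer minimum (only
#'   refined along axes whose both neighbours lie in the feasible set).
#'   The integer minimiser is unaffected.
#' @return List with `dx`, `dy` (integer shift), `epsilon` (criterion value
#'   at the minimum) and `n_candidates` (size of the feasible search set);
#'   plus `dx_sub`, `dy_sub` when `subpixel = TRUE`.
#' @export
match_block <- function(frame_t, frame_t1, r, radius = 8L, weight = NULL,
                        subpixel = FALSE) {
  stopifnot(inherits(r, "roi"))
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  shape <- dim(frame_t)
  if (!identical(shape, dim(frame_t1)))
    stop("frames must share one geometry", call. = FALSE)
  if (!.roi_in_frame(r, shape))
    stop(sprintf("ROI '%s' lies outside the frame", r$label), call. = FALSE)
  if (anyNA(frame_t) || anyNA(frame_t1))
    stop("frames contain NA intensities", call. = FALSE)
  template <- .roi_block(frame_t, r)
  if (!is.null(weight)) {
    if (!identical(dim(weight), dim(template)))
      stop("weight must match the ROI extent", call. = FALSE)
  }
  dxs <- seq(-radius, radius)
  feas_x <- dxs[r$x0 + dxs >= 0L & r$x0 + dxs + r$width <= shape[2]]
  feas_y <- dxs[r$y0 + dxs >= 0L & r$y0 + dxs + r$height <= shape[1]]
  if (length(feas_x) == 0L || length(feas_y) == 0L)
    stop("no feasible shift: ROI plus radius leaves the frame", call. = FALSE)
  eps_surf <- matrix(NA_real_, length(feas_y), length(feas_x))
  best <- NULL
  for (iy in seq_along(feas_y)) for (ix in seq_along(feas_x)) {
    dy <- feas_y[iy]; dx <- feas_x[ix]
    cand <- frame_t1[r$y0 + dy + seq_len(r$height),
                     r$x0 + dx + seq_len(r$width), drop = FALSE]
    dsq <- (template - cand)^2
    eps <- if (is.null(weight)) sum(dsq) else sum(dsq * weight)
    eps_surf[iy, ix] <- eps
    key <- c(eps, dx * dx + dy * dy, dy, dx)
    if (is.null(best) || .lex_less(key, best$key))
      best <- list(dx = dx, dy = dy, epsilon = eps, key = key,
                   iy = iy, ix = ix)
  }
  out <- list(dx = best$dx, dy = best$dy, epsilon = best$epsilon,
              n_candidates = length(feas_x) * length(feas_y))
  if (subpixel) {
    out$dx_sub <- best$dx + .parabolic_offset(eps_surf[best$iy, ],
                                              best$ix)
    out$dy_sub <- best$dy + .parabolic_offset(eps_surf[, best$ix],
                                              best$iy)
  }
  out
}

# vertex offset of the parabola through (i-1, i, i+1); 0 at the edge of
# the feasible set or on a flat surface
.parabolic_offset <- function(eps_line, i) {
  if (i <= 1L || i >= length(eps_line)) return(0)
  e0 <- eps_line[i - 1L]; e1 <- eps_line[i]; e2 <- eps_line[i + 1L]
  den <- e0 - 2 * e1 + e2
  if (den <= 0) return(0)
  off <- 0.5 * (e0 - e2) / den
  max(-0.5, min(0.5, off))
}

# strict lexicographic comparison of equal-length numeric keys
.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Track an ROI across a sequence
#'
#' Applies [match_block()] frame by frame.  By default the template is
#' adaptive: after each step the block is re-sampled from its newly matched
#' position in the newer frame, following the evolving speckle pattern.
#' The exhaustive search never moves the ROI outside the frame; a step is
#' flagged as clamped when the frame boundary clipped the search set and
#' the minimiser lies on that clipped edge, i.e. the true motion may have
#' exceeded what the frame allows.
#'
#' @param sequence An [image_sequence()].
#' @param r An [roi()] defined in the first frame.
#' @param radius Search radius per step (pixels).
#' @param weight Optional ROI-sized weight matrix (see [match_block()]).
#' @param adaptive If `FALSE`, the first-frame template is kept fixed and
#'   matched against each subsequent frame from the current position.
#' @return Object of class `"displacement_track"`: data frame `steps` with
#'   columns frame (index of the newer frame), dx, dy, epsilon, clamped;
#'   plus `positions` (cumulative 0-based x0/y0 per frame) and `roi`.
#' @export
track_roi <- function(sequence, r, radius = 8L, weight = NULL,
                      adaptive = TRUE) {
  stopifnot(inherits(sequence, "image_sequence"), inherits(r, "roi"))
  shape <- dim(sequence$frames)[1:2]
  if (!.roi_in_frame(r, shape))
    stop(sprintf("ROI '%s' lies outside the first frame", r$label),
         call. = FALSE)
  F_ <- n_frames(sequence)
  cur <- r
  template_frame <- sequence$frames[, , 1L]
  steps <- data.frame(frame = integer(0), dx = integer(0), dy = integer(0),
                      epsilon = numeric(0), clamped = logical(0))
  pos <- data.frame(frame = seq_len(F_), x0 = NA_integer_, y0 = NA_integer_)
  pos$x0[1] <- cur$x0; pos$y0[1] <- cur$y0
  for (f in 2:F_) {
    nxt <- sequence$frames[, , f]
    m <- match_block(template_frame, nxt, cur, radius = radius,
                     weight = weight)
    # pinned against a boundary-clipped edge of the search set?
    fx_lo <- max(-radius, -cur$x0)
    fx_hi <- min(radius, shape[2] - cur$width - cur$x0)
    fy_lo <- max(-radius, -cur$y0)
    fy_hi <- min(radius, shape[1] - cur$height - cur$y0)
    clamped <- (m$dx == fx_lo && fx_lo > -radius) ||
      (m$dx == fx_hi && fx_hi < radius) ||
      (m$dy == fy_lo && fy_lo > -radius) ||
      (m$dy == fy_hi && fy_hi < radius)
    cur <- roi(cur$x0 + m$dx, cur$y0 + m$dy, cur$width, cur$height,
               cur$label)
    steps <- rbind(steps, data.frame(frame = f, dx = m$dx, dy = m$dy,
                                     epsilon = m$epsilon, clamped = clamped))
    pos$x0[f] <- cur$x0; pos$y0[f] <- cur$y0
    if (adaptive) template_frame <- nxt
  }
  structure(list(steps = steps, positions = pos, roi = r,
                 frame_rate_hz = sequence$frame_rate_hz),
            class = "displacement_track")
}

#' @export
print.displacement_track <- function(x, ...) {
  cat(sprintf("Track '%s': %d steps, cumulative (%+d, %+d) px%s\n",
              x$roi$label, nrow(x$steps), sum(x$steps$dx), sum(x$steps$dy),
              if (any(x$steps$clamped)) " [clamped steps]" else ""))
  invisible(x)
}

#' Summarise tracks as a vector flow field
#'
#' Computes, for each tracked region, the mean per-step displacement vector
#' over a frame interval (a movement phase).  Regions with clamped steps in
#' the interval are marked unreliable.
#'
#' @param tracks A list of [track_roi()] results.
#' @param interval Integer `c(first, last)` frame range (newer-frame step
#'   indices, i.e. values appearing in `steps$frame`).
#' @return Data frame with columns roi_label, interval_start, interval_end,
#'   mean_dx, mean_dy, reliable.
#' @export
vector_flow_field <- function(tracks, interval) {
  if (inherits(tracks, "displacement_track")) tracks <- list(tracks)
  interval <- as.integer(interval)
  if (length(interval) != 2L || interval[1] > interval[2])
    stop("interval must be c(first, last) with first <= last", call. = FALSE)
  rows <- lapply(tracks, function(tr) {
    sel <- tr$steps$frame >= interval[1] & tr$steps$frame <= interval[2]
    if (!any(sel)) stop("interval contains no tracked steps", call. = FALSE)
    data.frame(roi_label = tr$roi$label,
               interval_start = interval[1], interval_end = interval[2],
               mean_dx = mean(tr$steps$dx[sel]),
               mean_dy = mean(tr$steps$dy[sel]),
               reliable = !any(tr$steps$clamped[sel]))
  })
  do.call(rbind, rows)
}

# -- serialisation ------------------------------------------------------------

#' Read ROI definitions from JSON
#'
#' The file is a JSON list of objects `{label, x0, y0, width, height}`.
#'
#' @param path JSON path.
#' @return List of [roi()] objects.
#' @export
read_rois_json <- function(path) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(defs, function(d)
    roi(d$x0, d$y0, d$width, d$height, label = d$label))
}

#' Export tracks and flow fields as CSV
#'
#' @param tracks List of [track_roi()] results.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "displacement_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    cum_x <- tr$positions$x0[-1]     # clamped cumulative position
    cum_y <- tr$positions$y0[-1]
    data.frame(frame_index = tr$steps$frame, roi_label = tr$roi$label,
               dx = tr$steps$dx, dy = tr$steps$dy,
               cum_x = cum_x, cum_y = cum_y,
               epsilon = tr$steps$epsilon, clamped = tr$steps$clamped)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tracks_csv
#' @param field A [vector_flow_field()] data frame.
#' @export
write_flow_field_csv <- function(field, path) {
  utils::write.csv(field, path, row.names = FALSE)
  invisible(field)
}
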