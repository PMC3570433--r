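# Synthetic B-mode-like speckle sequences with known latent kinematics.
#
# The speckle model is a scatterer-convolution construction: a random point
# scatterer field convolved with a Gaussian point-spread kernel and envelope
# rectified.  It is deliberately non-physical (no beamforming, no
# depth-dependent PSF) -- just enough texture statistics to exercise wavelet
# compression and block matching.  Tissue motion is piecewise-rigid per
# rectangular region with a smooth linear falloff band at region borders so
# warp seams do not dominate the wavelet features.

# run code under a local RNG state (R's Mersenne-Twister; identical across
# platforms) without disturbing the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# 1-D Gaussian convolution matrix (truncated at 4 sigma, replicated edges)
.gauss_conv_mat <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    M[cbind(seq_len(n), src)] <- M[cbind(seq_len(n), src)] + k[j]
  }
  M
}

#' Generate a synthetic speckle texture
#'
#' Draws a sparse random point-scatterer field (fraction `scatterer_density`
#' of pixels carry a scatterer with a positive half-normal amplitude),
#' convolves it with a separable Gaussian point-spread kernel of width
#' `psf_sigma` pixels, envelope-rectifies and rescales to the 0-255
#' intensity range.  Deterministic per seed.
#'
#' @param shape Integer `c(H, W)`.
#' @param scatterer_density Fraction of pixels carrying a scatterer
#'   (default 0.1).
#' @param psf_sigma Gaussian PSF standard deviation in pixels (default 1.2;
#'   sets the speckle correlation length).
#' @param seed Integer RNG seed.
#' @return Numeric H x W matrix of intensities in \[0, 255\].
#' @examples
#' tex <- make_speckle_texture(c(64, 64), seed = 1)
#' range(tex)
#' @export
make_speckle_texture <- function(shape, scatterer_density = 0.1,
                                 psf_sigma = 1.2, seed = 1L) {
  if (scatterer_density <= 0) stop("scatterer_density must be > 0",
                                   call. = FALSE)
  if (psf_sigma <= 0) stop("psf_sigma must be > 0", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  .with_seed(seed, {
    field <- matrix(0, H, W)
    hit <- stats::runif(H * W) < scatterer_density
    field[hit] <- abs(stats::rnorm(sum(hit)))
    img <- .gauss_conv_mat(H, psf_sigma) %*% field %*%
      t(.gauss_conv_mat(W, psf_sigma))
    img <- abs(img)
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1]) * 255
    img
  })
}

#' Define a labelled motion region
#'
#' A rectangle (0-based pixel coordinates, half-open extent) whose content
#' translates with the latent movement course, scaled by per-region
#' amplitudes.
#'
#' @param label Region name.
#' @param x0,y0 Top-left corner (0-based column / row).
#' @param width,height Extent in pixels.
#' @param amp_x,amp_y Peak displacement in pixels along x (columns) and y
#'   (rows) when the latent course equals 1.
#' @return A list of class `"motion_region"`.
#' @export
motion_region <- function(label, x0, y0, width, height,
                          amp_x = 0, amp_y = 0) {
  structure(list(label = label, x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 amp_x = amp_x, amp_y = amp_y),
            class = "motion_region")
}

#' Scenario specification for the synthetic generator
#'
#' Describes one synthetic capture: image geometry, frame count and rate,
#' moving regions, the latent movement course, an optional block-unique
#' twitch event, and the noise level.
#'
#' The default latent course (`latent = NULL`) is a smooth two-repeat
#' movement `u(t) = (1 - cos(2 pi cycles t/(F-1)))/2` in \[0, 1\] with
#' `cycles = 2`, emulating a movement performed twice within the capture;
#' its interior extrema are the recorded phase boundaries.
#'
#' @param shape `c(H, W)` image size (default `c(64, 64)`).
#' @param n_frames Frame count F (default 150).
#' @param frame_rate_hz Emulated acquisition rate (default 78.6).
#' @param regions List of [motion_region()]s; `NULL` for a standard
#'   three-layer layout scaled to `shape`.
#' @param latent Optional numeric length-F latent course; overrides
#'   `cycles`/`phase` if given.
#' @param cycles Number of movement repeats in the default course.
#' @param phase Phase offset (radians) of the default course.
#' @param twitch `NULL`, or a list `list(region =, onset =, duration =,
#'   amp_x =, amp_y =)` adding a transient Hann-profiled displacement to one
#'   region (the block-unique event).
#' @param noise_sd Additive Gaussian intensity noise (0-255 scale;
#'   default 5).
#' @param scatterer_density,psf_sigma Texture parameters
#'   (see [make_speckle_texture()]).
#' @param falloff Width in pixels of the linear motion falloff band at
#'   region borders (default 4; 0 in integer mode).
#' @param integer_motion If `TRUE`, displacements are rounded to whole
#'   pixels and frames are warped by exact integer shifts (no
#'   interpolation), giving ground truth a block tracker can match exactly.
#' @param seed Integer RNG seed for texture and noise.
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(shape = c(64L, 64L), n_frames = 150L,
                          frame_rate_hz = 78.6, regions = NULL,
                          latent = NULL, cycles = 2, phase = 0,
                          twitch = NULL, noise_sd = 5,
                          scatterer_density = 0.1, psf_sigma = 1.2,
                          falloff = 4L, integer_motion = FALSE, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(regions)) regions <- .default_regions(shape)
  if (!is.null(latent) && length(latent) != n_frames)
    stop("latent course must have length n_frames", call. = FALSE)
  sp <- structure(list(shape = as.integer(shape), n_frames = n_frames,
                       frame_rate_hz = frame_rate_hz, regions = regions,
                       latent = latent, cycles = cycles, phase = phase,
                       twitch = twitch, noise_sd = noise_sd,
                       scatterer_density = scatterer_density,
                       psf_sigma = psf_sigma,
                       falloff = if (integer_motion) 0L else as.integer(falloff),
                       integer_motion = integer_motion,
                       seed = as.integer(seed)),
                  class = "scenario_spec")
  .validate_scenario(sp)
  sp
}

# three tissue layers: deep structures move most (aponeurosis-like), the
# superficial layer least
.default_regions <- function(shape) {
  H <- shape[1]; W <- shape[2]
  x0 <- round(W * 0.12); w <- round(W * 0.72)
  list(
    motion_region("superficial", x0, round(H * 0.08), w, round(H * 0.22),
                  amp_x = 0.8, amp_y = 0.1),
    motion_region("middle", x0, round(H * 0.36), w, round(H * 0.24),
                  amp_x = 1.8, amp_y = 0.3),
    motion_region("deep", x0, round(H * 0.66), w, round(H * 0.24),
                  amp_x = 3.0, amp_y = 0.6)
  )
}

.latent_course <- function(spec) {
  if (!is.null(spec$latent)) return(spec$latent)
  t <- seq_len(spec$n_frames) - 1L
  (1 - cos(2 * pi * spec$cycles * t / (spec$n_frames - 1L) + spec$phase)) / 2
}

# interior extrema (turning points) of the latent course
.phase_boundaries <- function(u) {
  d <- diff(u)
  s <- sign(d)
  s[s == 0] <- NA
  s <- .na_locf(s)
  which(diff(s) != 0) + 1L  # 1-based frame index of the turning frame
}

# last-observation-carried-forward; leading NAs are back-filled
.na_locf <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  idx <- cumsum(!is.na(x))
  x[idx > 0] <- x[ok][idx[idx > 0]]
  if (idx[1] == 0) x[seq_len(which(idx > 0)[1] - 1L)] <- x[ok][1]
  x
}

.twitch_course <- function(spec) {
  F_ <- spec$n_frames
  out <- numeric(F_)
  tw <- spec$twitch
  if (is.null(tw)) return(out)
  frames <- seq(tw$onset, min(F_, tw$onset + tw$duration - 1L))
  # Hann profile over the twitch window
  prof <- 0.5 * (1 - cos(2 * pi * (seq_along(frames) - 1L) /
                           (length(frames) - 1L)))
  out[frames] <- prof
  out
}

.validate_scenario <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  u <- .latent_course(spec)
  twc <- .twitch_course(spec)
  for (r in spec$regions) {
    if (r$x0 < 0 || r$y0 < 0 || r$x0 + r$width > W || r$y0 + r$height > H)
      stop(sprintf("region '%s' lies outside the %dx%d image", r$label, H, W),
           call. = FALSE)
    tx <- if (!is.null(spec$twitch) && identical(spec$twitch$region, r$label))
      spec$twitch$amp_x * twc else 0
    ty <- if (!is.null(spec$twitch) && identical(spec$twitch$region, r$label))
      spec$twitch$amp_y * twc else 0
    dx <- r$amp_x * u + tx; dy <- r$amp_y * u + ty
    pad <- spec$falloff
    if (min(r$x0 + dx) < -pad - 1 || max(r$x0 + r$width + dx) > W + pad + 1 ||
        min(r$y0 + dy) < -pad - 1 || max(r$y0 + r$height + dy) > H + pad + 1)
      stop(sprintf("region '%s' is displaced outside the image bounds",
                   r$label), call. = FALSE)
  }
  bnd <- .phase_boundaries(u)
  if (any(bnd < 1L | bnd > spec$n_frames))
    stop("phase boundaries must lie within the capture", call. = FALSE)
  invisible(TRUE)
}

# 1-D region weight profile: 1 on [a, b), linear falloff over `fw` px
.region_weight_1d <- function(n, a, b, fw) {
  x <- seq_len(n) - 1L
  if (fw <= 0) return(as.numeric(x >= a & x < b))
  pmax(0, pmin(1, pmin((x - a) / fw + 1, (b - 1 - x) / fw + 1)))
}

# bilinear backward warp: out(p) = img(p - d(p)), edge-replicated sampling
.warp_bilinear <- function(img, dxm, dym) {
  H <- nrow(img); W <- ncol(img)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  rows <- matrix(rep(seq_len(H), times = W), H, W)
  xs <- pmin(pmax(cols - dxm, 1), W)
  ys <- pmin(pmax(rows - dym, 1), H)
  x0 <- pmin(floor(xs), W - 1L); y0 <- pmin(floor(ys), H - 1L)
  fx <- xs - x0; fy <- ys - y0
  g <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x0 + 1) +
    (1 - fx) * fy * g(y0 + 1, x0) + fx * fy * g(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

# nearest/integer warp: exact pixel copy for integer displacement fields
.warp_integer <- function(img, dxm, dym) {
  H <- nrow(img); W <- ncol(img)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  rows <- matrix(rep(seq_len(H), times = W), H, W)
  xs <- pmin(pmax(cols - dxm, 1), W)
  ys <- pmin(pmax(rows - dym, 1), H)
  matrix(img[cbind(as.vector(ys), as.vector(xs))], H, W)
}

#' Generate a synthetic sequence with ground truth
#'
#' Builds the base speckle texture, then renders each frame by displacing
#' every region by its latent-course-scaled amplitude (plus the twitch, if
#' the region carries one) and adding Gaussian intensity noise.  The exact
#' latent course, per-region cumulative and per-step displacements, phase
#' boundaries and twitch course are returned as ground truth.
#'
#' @param spec A [scenario_spec()].
#' @return List with `sequence` (an [image_sequence()]) and `truth`, a list
#'   holding `latent` (length F), `phase_boundaries` (1-based frame
#'   indices of latent turning points), `twitch_course` (length F),
#'   `displacement` (data frame: frame, region, dx, dy cumulative pixels),
#'   and `steps` (data frame: frame, region, dx, dy per-step pixels, one
#'   row per frame transition 2..F).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .validate_scenario(spec)
  H <- spec$shape[1]; W <- spec$shape[2]
  F_ <- spec$n_frames
  base <- make_speckle_texture(spec$shape, spec$scatterer_density,
                               spec$psf_sigma, seed = spec$seed)
  u <- .latent_course(spec)
  twc <- .twitch_course(spec)
  disp <- vector("list", length(spec$regions))
  names(disp) <- vapply(spec$regions, `[[`, "", "label")
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    tx <- if (!is.null(spec$twitch) && identical(spec$twitch$region, r$label))
      spec$twitch$amp_x * twc else numeric(F_)
    ty <- if (!is.null(spec$twitch) && identical(spec$twitch$region, r$label))
      spec$twitch$amp_y * twc else numeric(F_)
    dx <- r$amp_x * u + tx
    dy <- r$amp_y * u + ty
    if (spec$integer_motion) { dx <- round(dx); dy <- round(dy) }
    disp[[i]] <- cbind(dx = dx, dy = dy)
  }
  noise <- .with_seed(spec$seed + 104729L,
                      array(stats::rnorm(H * W * F_, 0, spec$noise_sd),
                            c(H, W, F_)))
  frames <- array(0, c(H, W, F_))
  for (f in seq_len(F_)) {
    dxm <- matrix(0, H, W); dym <- matrix(0, H, W)
    for (i in seq_along(spec$regions)) {
      r <- spec$regions[[i]]
      dx <- disp[[i]][f, "dx"]; dy <- disp[[i]][f, "dy"]
      wx <- .region_weight_1d(W, r$x0 + dx, r$x0 + r$width + dx, spec$falloff)
      wy <- .region_weight_1d(H, r$y0 + dy, r$y0 + r$height + dy, spec$falloff)
      w2 <- outer(wy, wx)
      dxm <- dxm + w2 * dx
      dym <- dym + w2 * dy
    }
    warped <- if (spec$integer_motion) .warp_integer(base, round(dxm),
                                                     round(dym))
      else .warp_bilinear(base, dxm, dym)
    # clip to the displayable intensity range, as a B-mode capture would be
    frames[, , f] <- pmin(pmax(warped + noise[, , f], 0), 255)
  }
  dd <- do.call(rbind, lapply(seq_along(disp), function(i)
    data.frame(frame = seq_len(F_), region = names(disp)[i],
               dx = disp[[i]][, "dx"], dy = disp[[i]][, "dy"])))
  steps <- do.call(rbind, lapply(seq_along(disp), function(i)
    data.frame(frame = 2:F_, region = names(disp)[i],
               dx = diff(disp[[i]][, "dx"]), dy = diff(disp[[i]][, "dy"]))))
  list(sequence = image_sequence(frames, spec$frame_rate_hz,
                                 source_id = sprintf("synthetic-%d", spec$seed)),
       truth = list(latent = u,
                    phase_boundaries = .phase_boundaries(u),
                    twitch_course = twc,
                    displacement = dd,
                    steps = steps))
}

#' Generate a paired two-capture scenario
#'
#' The three named scenarios mirror the study designs the method targets:
#' \describe{
#'   \item{repeat}{Two captures of the same movement: identical latent
#'     course and region layout, independent speckle textures and noise.}
#'   \item{orthviews}{Two projections of the same movement: identical
#'     latent course, geometrically different region layouts, plus a
#'     transient twitch present in X only (the block-unique event).}
#'   \item{null}{No shared movement: independent latent courses (different
#'     harmonics of the capture length, random relative phase), so the two
#'     blocks share no joint variation.}
#' }
#'
#' @param scenario One of `"repeat"`, `"orthviews"`, `"null"`.
#' @param seed Integer seed controlling textures, noise and (for `null`)
#'   the relative phase.
#' @param n_frames,shape,noise_sd Overrides passed to [scenario_spec()].
#' @param integer_motion Use exact integer displacements (tracker tests).
#' @return List with `x`, `y` (the two [image_sequence()]s), `truth_x`,
#'   `truth_y` (per-block ground truth) and `spec_x`, `spec_y`.
#' @export
generate_pair <- function(scenario = c("repeat", "orthviews", "null"),
                          seed = 1L, n_frames = 150L, shape = c(64L, 64L),
                          noise_sd = 5, integer_motion = FALSE) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  common <- list(shape = shape, n_frames = n_frames, noise_sd = noise_sd,
                 integer_motion = integer_motion)
  if (scenario == "repeat") {
    sx <- do.call(scenario_spec, c(common, list(seed = seed * 2L + 11L)))
    sy <- do.call(scenario_spec, c(common, list(seed = seed * 2L + 12L)))
  } else if (scenario == "orthviews") {
    H <- shape[1]; W <- shape[2]
    # concentric rise, static hold (constant tension), eccentric return;
    # the twitch occurs during the hold, where the shared movement is
    # stationary
    t1 <- round(0.35 * (n_frames - 1L)); t2 <- round(0.75 * (n_frames - 1L))
    tt <- seq_len(n_frames) - 1L
    u <- ifelse(tt <= t1, (1 - cos(pi * tt / t1)) / 2,
                ifelse(tt <= t2, 1,
                       (1 + cos(pi * (tt - t2) / (n_frames - 1L - t2))) / 2))
    # longitudinal view: layered regions, mostly axial (x) motion;
    # short head carries the twitch
    reg_x <- list(
      motion_region("long_head", round(W * 0.10), round(H * 0.10),
                    round(W * 0.75), round(H * 0.30), amp_x = 2.5, amp_y = 0.5),
      motion_region("short_head", round(W * 0.10), round(H * 0.55),
                    round(W * 0.75), round(H * 0.30), amp_x = 1.5, amp_y = 0.4))
    # transversal view: side-by-side cross-sections, mostly vertical
    # thickening
    reg_y <- list(
      motion_region("cross_med", round(W * 0.08), round(H * 0.25),
                    round(W * 0.36), round(H * 0.45), amp_x = 0.4, amp_y = 2.0),
      motion_region("cross_lat", round(W * 0.54), round(H * 0.30),
                    round(W * 0.36), round(H * 0.45), amp_x = -0.3, amp_y = 1.4))
    twitch <- list(region = "short_head", onset = round(n_frames * 0.50),
                   duration = max(6L, round(n_frames * 0.13)),
                   amp_x = 0.6, amp_y = 2.0)
    sx <- do.call(scenario_spec, c(common, list(regions = reg_x,
                                                latent = u,
                                                twitch = twitch,
                                                seed = seed * 2L + 21L)))
    sy <- do.call(scenario_spec, c(common, list(regions = reg_y,
                                                latent = u,
                                                seed = seed * 2L + 22L)))
  } else {
    phi <- .with_seed(seed * 2L + 31L, stats::runif(1, 0, 2 * pi))
    sx <- do.call(scenario_spec, c(common, list(cycles = 2,
                                                seed = seed * 2L + 32L)))
    sy <- do.call(scenario_spec, c(common, list(cycles = 3, phase = phi,
                                                seed = seed * 2L + 33L)))
  }
  gx <- generate_sequence(sx)
  gy <- generate_sequence(sy)
  list(x = gx$sequence, y = gy$sequence,
       truth_x = gx$truth, truth_y = gy$truth,
       spec_x = sx, spec_y = sy, scenario = scenario, seed = seed)
}

#' Write a generated scenario to disk
#'
#' Writes each sequence as a multi-page TIFF, the ground truth as CSVs and
#' the resolved scenario parameters as JSON.
#'
#' @param pair A [generate_pair()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequence_tiff(pair$x, file.path(dir, "sequence_x.tiff"))
  write_sequence_tiff(pair$y, file.path(dir, "sequence_y.tiff"))
  for (blk in c("x", "y")) {
    tr <- pair[[paste0("truth_", blk)]]
    utils::write.csv(data.frame(frame = seq_along(tr$latent),
                                latent = tr$latent,
                                twitch = tr$twitch_course),
                     file.path(dir, sprintf("latent_%s.csv", blk)),
                     row.names = FALSE)
    utils::write.csv(tr$displacement,
                     file.path(dir, sprintf("displacement_%s.csv", blk)),
                     row.names = FALSE)
  }
  spec_out <- lapply(pair[c("spec_x", "spec_y")], function(s) {
    s$regions <- lapply(s$regions, unclass)
    unclass(s)
  })
  spec_out$scenario <- pair$scenario
  spec_out$seed <- pair$seed
  jsonlite::write_json(spec_out, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
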