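# End-to-end orchestration: synchronise two captures, build feature tables,
# cross-validate and fit O2PLS, segment movement phases from score vectors,
# and write a reproducible analysis bundle.

#' Synchronisation specification
#'
#' Marks the first and last frame of the movement within a longer capture
#' and the frame count of the reference capture it must be aligned to.
#'
#' @param begin_frame,end_frame 0-based first/last movement frame
#'   (`begin_frame < end_frame`).
#' @param target_length Number of frames to keep (>= 2, at most
#'   `end_frame - begin_frame + 1`).
#' @return Object of class `"sync_spec"`.
#' @export
sync_spec <- function(begin_frame, end_frame, target_length) {
  s <- structure(list(begin_frame = as.integer(begin_frame),
                      end_frame = as.integer(end_frame),
                      target_length = as.integer(target_length)),
                 class = "sync_spec")
  if (s$begin_frame < 0L)
    stop("begin_frame must be >= 0", call. = FALSE)
  if (s$end_frame <= s$begin_frame)
    stop("end_frame must exceed begin_frame", call. = FALSE)
  if (s$target_length < 2L)
    stop("target_length must be >= 2", call. = FALSE)
  if (s$target_length > s$end_frame - s$begin_frame + 1L)
    stop("target_length exceeds the spanned frame count", call. = FALSE)
  s
}

# round half away from zero (R's round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Synchronise a capture to a target length
#'
#' Keeps `target_length` frames spaced linearly between `begin_frame` and
#' `end_frame`, i.e. frames at indices
#' `round(begin + i (end - begin) / (target_length - 1))` for
#' `i = 0 .. target_length - 1` (rounding half away from zero) -- the
#' linear frame-removal rule used to align a longer capture with a shorter
#' reference.  Endpoints are kept exactly.
#'
#' @param sequence An [image_sequence()].
#' @param spec A [sync_spec()]; `end_frame` must lie within the capture.
#' @return The synchronised [image_sequence()].
#' @export
synchronize <- function(sequence, spec) {
  stopifnot(inherits(sequence, "image_sequence"), inherits(spec, "sync_spec"))
  F_ <- n_frames(sequence)
  if (spec$end_frame >= F_)
    stop(sprintf("end_frame %d is outside the %d-frame capture",
                 spec$end_frame, F_), call. = FALSE)
  idx <- sync_indices(spec)
  image_sequence(sequence$frames[, , idx + 1L, drop = FALSE],
                 frame_rate_hz = sequence$frame_rate_hz,
                 source_id = paste0(sequence$source_id, "-synced"))
}

#' @rdname synchronize
#' @return `sync_indices()`: the 0-based frame indices that are kept.
#' @export
sync_indices <- function(spec) {
  stopifnot(inherits(spec, "sync_spec"))
  i <- seq_len(spec$target_length) - 1L
  as.integer(.round_half_away(
    spec$begin_frame +
      i * (spec$end_frame - spec$begin_frame) / (spec$target_length - 1L)))
}

#' Segment a score vector into movement phases
#'
#' Smooths the score with a centered moving average and places phase
#' boundaries at interior local extrema (turning points of the movement),
#' keeping extrema at least `min_separation` seconds apart (larger
#' deviations from the mean win).  A monotone score yields a single
#' segment.
#'
#' @param score Numeric score vector over frames (length >= 5).
#' @param times Frame times in seconds (default from `frame_rate_hz`).
#' @param min_separation Minimum spacing between boundaries in seconds.
#' @param window Moving-average window in frames (odd; default 5).
#' @param frame_rate_hz Used when `times` is `NULL`.
#' @return Object of class `"phase_segmentation"`: `boundaries` (1-based
#'   interior frame indices, strictly increasing), `labels` (one per
#'   segment), `source` description.
#' @export
detect_phases <- function(score, times = NULL, min_separation = 0.25,
                          window = 5L, frame_rate_hz = 78.6,
                          source = "score") {
  F_ <- length(score)
  if (F_ < 5L) stop("need at least 5 frames", call. = FALSE)
  if (min_separation <= 0) stop("min_separation must be > 0", call. = FALSE)
  if (is.null(times)) times <- (seq_len(F_) - 1L) / frame_rate_hz
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  sm <- stats::filter(score, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  # candidates: interior sign changes of the first difference
  valid <- (half + 1L):(F_ - half)
  d <- diff(sm[valid])
  s <- sign(d); s[s == 0] <- NA; s <- .na_locf(s)
  turn <- which(diff(s) != 0) + 1L
  cand <- valid[turn]
  if (length(cand) > 0L) {
    # greedy prominence: larger |deviation from the mean| wins ties for
    # spacing
    prom <- abs(sm[cand] - mean(sm, na.rm = TRUE))
    keep <- integer(0)
    for (i in order(-prom)) {
      if (all(abs(times[cand[i]] - times[keep]) >= min_separation) ||
          length(keep) == 0L)
        keep <- c(keep, cand[i])
    }
    cand <- sort(keep)
  }
  labels <- paste0("phase_", seq_len(length(cand) + 1L))
  structure(list(boundaries = cand, labels = labels, source = source,
                 times = times), class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("Phase segmentation from %s: %d segment(s)\n", x$source,
              length(x$labels)))
  if (length(x$boundaries))
    cat("  boundaries at frames:", paste(x$boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' Join score vectors with an auxiliary per-frame channel
#'
#' Merges a tidy score table (see [export_scores()]) with a per-frame
#' scalar channel such as a goniometer angle, by frame index or by nearest
#' time (within half a frame period), and reports the correlation between
#' each score column and the auxiliary.
#'
#' @param scores Tidy score data frame with columns frame_index, time_s,
#'   component, block, kind, value.
#' @param aux Data frame with column `value` plus either `frame_index` or
#'   `time_s`.
#' @return List with `merged` (scores plus `aux_value` column) and
#'   `correlations` (data frame block/kind/component/correlation, with a
#'   `zero_variance` flag where the correlation is undefined).
#' @export
overlay_auxiliary <- function(scores, aux) {
  if (!all(c("frame_index", "value") %in% names(aux))) {
    if (!all(c("time_s", "value") %in% names(aux)))
      stop("aux needs columns value plus frame_index or time_s",
           call. = FALSE)
    # nearest-time join within half a frame period
    ft <- sort(unique(scores$time_s))
    period <- if (length(ft) > 1L) min(diff(ft)) else 1
    fi <- vapply(aux$time_s, function(tt) {
      j <- which.min(abs(ft - tt))
      if (abs(ft[j] - tt) > period / 2)
        stop("auxiliary time base cannot be joined to the frame times",
             call. = FALSE)
      j
    }, numeric(1))
    aux$frame_index <- as.integer(fi)
  }
  if (anyDuplicated(aux$frame_index))
    stop("auxiliary channel has duplicate frames", call. = FALSE)
  lut <- rep(NA_real_, max(scores$frame_index))
  lut[aux$frame_index] <- aux$value
  merged <- scores
  merged$aux_value <- lut[merged$frame_index]
  if (anyNA(merged$aux_value))
    stop("auxiliary channel does not cover every frame", call. = FALSE)
  key <- unique(merged[, c("block", "kind", "component")])
  cors <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- merged$block == key$block[i] & merged$kind == key$kind[i] &
      merged$component == key$component[i]
    v <- merged$value[sel]; a <- merged$aux_value[sel]
    zv <- stats::sd(v) == 0 || stats::sd(a) == 0
    data.frame(block = key$block[i], kind = key$kind[i],
               component = key$component[i],
               correlation = if (zv) 0 else stats::cor(v, a),
               zero_variance = zv)
  }))
  list(merged = merged, correlations = cors)
}

#' Default run configuration
#'
#' Returns the resolved configuration list used by [run_maci_o2pls()],
#' optionally overridden from a YAML or JSON file and/or a named list.
#'
#' @param file Optional YAML/JSON config path.
#' @param overrides Optional named list merged over the file values.
#' @return Nested configuration list.
#' @export
maci_config <- function(file = NULL, overrides = NULL) {
  cfg <- list(
    wavelet = list(family = "sym8", levels = 3L, boundary_mode = "symmetric"),
    features = list(n = NULL, variance_fraction = 0.95, max_n = 10000L,
                    exclude_approx = FALSE),
    o2pls = list(max_k = 5L, max_l = 3L, max_m = 3L, folds = 7L,
                 threshold = 0.01, center = TRUE, block_scaling = FALSE),
    phases = list(window = 5L, min_separation = 0.25),
    sync_x = NULL, sync_y = NULL)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    vals <- if (ext == "json") jsonlite::read_json(file, simplifyVector = TRUE)
      else yaml::read_yaml(file)
    cfg <- merge_in(cfg, vals)
  }
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  cfg
}

#' Run the full two-sequence analysis
#'
#' Orchestrates the method end to end: optional synchronisation, wavelet
#' feature tables for both captures, cross-validated component selection,
#' the final O2PLS fit, variance report, joint score correlations and phase
#' segmentation of the first joint score vector.  With `out` set, the
#' bundle is written to disk (tidy score CSV, feature tables, model
#' directory, loading images as PNG, resolved config and a checksum
#' manifest).
#'
#' @param seq_x,seq_y The two [image_sequence()] captures.
#' @param config A [maci_config()] list.
#' @param out Optional output directory.
#' @return List of class `"maci_analysis"`: `features_x`, `features_y`,
#'   `cv`, `model`, `variance`, `score_correlations`, `phases`, `scores`
#'   (tidy data frame), `config`.
#' @export
run_maci_o2pls <- function(seq_x, seq_y, config = maci_config(),
                           out = NULL) {
  stopifnot(inherits(seq_x, "image_sequence"),
            inherits(seq_y, "image_sequence"))
  if (!is.null(config$sync_x))
    seq_x <- synchronize(seq_x, do.call(sync_spec, config$sync_x))
  if (!is.null(config$sync_y))
    seq_y <- synchronize(seq_y, do.call(sync_spec, config$sync_y))
  if (n_frames(seq_x) != n_frames(seq_y))
    stop(sprintf(paste0("captures have %d and %d frames; provide sync_x/",
                        "sync_y specs to synchronise them"),
                 n_frames(seq_x), n_frames(seq_y)), call. = FALSE)
  ws <- wavelet_spec(config$wavelet$family, config$wavelet$levels,
                     config$wavelet$boundary_mode)
  ft_x <- build_feature_table(seq_x, ws, n = config$features$n,
                              variance_fraction = config$features$variance_fraction,
                              max_n = config$features$max_n,
                              exclude_approx = config$features$exclude_approx)
  ft_y <- build_feature_table(seq_y, ws, n = config$features$n,
                              variance_fraction = config$features$variance_fraction,
                              max_n = config$features$max_n,
                              exclude_approx = config$features$exclude_approx)
  oc <- config$o2pls
  cv <- cross_validate(ft_x, ft_y, max_k = oc$max_k, max_l = oc$max_l,
                       max_m = oc$max_m, folds = oc$folds,
                       threshold = oc$threshold, center = oc$center,
                       block_scaling = oc$block_scaling)
  model <- NULL; varrep <- NULL; sc <- numeric(0); phases <- NULL
  scores <- NULL
  if (!cv$no_joint_variation) {
    s <- cv$selected
    model <- fit_o2pls(ft_x, ft_y, k = s["k"], l = s["l"], m = s["m"],
                       center = oc$center, block_scaling = oc$block_scaling)
    varrep <- explained_variance(model, ft_x, ft_y)
    sc <- score_correlations(model)
    scores <- export_scores(model, frame_rate_hz = seq_x$frame_rate_hz)
    phases <- detect_phases(model$Tmat[, 1L],
                            times = frame_times(seq_x),
                            min_separation = config$phases$min_separation,
                            window = config$phases$window,
                            frame_rate_hz = seq_x$frame_rate_hz,
                            source = "T1")
  }
  res <- structure(list(features_x = ft_x, features_y = ft_y, cv = cv,
                        model = model, variance = varrep,
                        score_correlations = sc, phases = phases,
                        scores = scores, config = config),
                   class = "maci_analysis")
  if (!is.null(out)) .write_bundle(res, out)
  res
}

#' @export
print.maci_analysis <- function(x, ...) {
  print(x$cv)
  if (!is.null(x$model)) {
    print(x$model)
    print(x$variance)
    if (!is.null(x$phases)) print(x$phases)
  }
  invisible(x)
}

# normalise a loading image to [0,1] for PNG export (symmetric about zero)
.loading_png <- function(img) {
  a <- max(abs(img))
  if (a == 0) a <- 1
  (img / a + 1) / 2
}

.write_bundle <- function(res, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(res$features_x, file.path(out, "features_x.csv"))
  write_feature_table(res$features_y, file.path(out, "features_y.csv"))
  utils::write.csv(res$cv$grid, file.path(out, "cv_grid.csv"),
                   row.names = FALSE)
  writeLines(res$cv$rule_trace, file.path(out, "cv_trace.txt"))
  if (!is.null(res$model)) {
    write_o2pls(res$model, file.path(out, "model"))
    utils::write.csv(res$scores, file.path(out, "scores.csv"),
                     row.names = FALSE)
    vr <- res$variance
    jsonlite::write_json(
      list(r2x_joint = vr$r2x_joint, r2x_orth = vr$r2x_orth,
           r2x_resid = vr$r2x_resid, r2y_joint = vr$r2y_joint,
           r2y_orth = vr$r2y_orth, r2y_resid = vr$r2y_resid,
           score_correlations = res$score_correlations,
           phase_boundaries = res$phases$boundaries),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
    for (i in seq_len(min(res$model$k, 2L))) {
      img <- loading_to_image(res$model$P[, i], res$features_x)
      png::writePNG(.loading_png(img),
                    file.path(out, sprintf("loading_x_joint%d.png", i)))
    }
    if (res$model$l > 0L) {
      img <- loading_to_image(res$model$Po[, 1L], res$features_x)
      png::writePNG(.loading_png(img),
                    file.path(out, "loading_x_orth1.png"))
    }
  }
  jsonlite::write_json(res$config, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA)
  invisible(out)
}
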