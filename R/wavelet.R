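# 2D discrete wavelet transform, coefficient selection, and the congruent
# feature table.
#
# The transform is implemented directly from the orthonormal filter banks
# (Symlet 8 by default).  Two boundary modes are provided:
#   * "symmetric"     -- half-point symmetric extension; redundant (each 1-D
#                        pass of length N yields floor((N + L - 1)/2)
#                        coefficients per subband, so the coefficient count
#                        can exceed H*W) but perfectly invertible.
#   * "periodization" -- circular extension for even lengths; the transform
#                        matrix is orthogonal, so energy is preserved exactly.

# Orthonormal decomposition filters (low-pass).  High-pass and synthesis
# filters are derived by quadrature-mirror relations below.
.maci_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
           0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
           0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
           -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
           0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
           0.0018899503327594609)
)

.subband_names <- c("approx", "horiz", "vert", "diag")

#' Wavelet decomposition settings
#'
#' Bundles the wavelet family, number of decomposition levels and boundary
#' handling used to transform every frame of a sequence.  The same spec must
#' be used for analysis, synthesis and loading back-projection so that
#' coefficient indices stay congruent across frames.
#'
#' @param family Wavelet family: one of `"sym8"` (default, 16-tap near
#'   symmetric orthogonal filters), `"db4"` or `"haar"`.
#' @param levels Number of decomposition levels (integer >= 1).
#' @param boundary_mode `"symmetric"` (half-point symmetric padding, the
#'   default) or `"periodization"` (circular; requires even subband sizes,
#'   preserves energy exactly).
#' @return An object of class `"wavelet_spec"`.
#' @examples
#' ws <- wavelet_spec("sym8", levels = 2)
#' max_dwt_levels(c(256, 256), ws)
#' @export
wavelet_spec <- function(family = "sym8", levels = 3L,
                         boundary_mode = c("symmetric", "periodization")) {
  family <- match.arg(family, names(.maci_filters))
  boundary_mode <- match.arg(boundary_mode)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L)
    stop("`levels` must be an integer >= 1", call. = FALSE)
  structure(list(family = family, levels = levels,
                 boundary_mode = boundary_mode),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("Wavelet spec: %s, %d level(s), %s boundary\n",
              x$family, x$levels, x$boundary_mode))
  invisible(x)
}

.wav_filters <- function(family) {
  lo <- .maci_filters[[family]]
  L <- length(lo)
  # quadrature mirror: hi[j] = (-1)^(j+1) lo[L-1-j]  (0-based j)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi), L = L)
}

#' Maximum admissible decomposition depth
#'
#' The deepest level for which the coarsest subband still spans at least one
#' full filter length: `floor(log2(min(H, W) / (L - 1)))` for an `L`-tap
#' family.
#'
#' @param shape Integer vector `c(H, W)`.
#' @param spec A [wavelet_spec()] (only the family matters).
#' @return Integer maximum level (possibly 0 if the image is too small).
#' @export
max_dwt_levels <- function(shape, spec) {
  L <- .wav_filters(spec$family)$L
  m <- min(shape) / (L - 1)
  if (m < 2) return(0L)
  as.integer(floor(log2(m)))
}

.check_levels <- function(shape, spec) {
  mx <- max_dwt_levels(shape, spec)
  if (spec$levels > mx)
    stop(sprintf(paste0("image of size %dx%d admits at most %d %s ",
                        "decomposition level(s); %d requested"),
                 shape[1], shape[2], mx, spec$family, spec$levels),
         call. = FALSE)
  invisible(TRUE)
}

# -- 1-D analysis/synthesis along the rows of a matrix ------------------------

# half-point symmetric index reflection into 1..n
.reflect_idx <- function(i, n) {
  # i may lie outside 1..n; reflect repeatedly
  while (any(bad <- (i < 1L | i > n))) {
    i[bad & i < 1L] <- 1L - i[bad & i < 1L]
    bad2 <- i > n
    i[bad2] <- 2L * n + 1L - i[bad2]
  }
  i
}

# analysis of every column of M (length N) -> list(a, d) with
# out_len rows each.  Convention (verified against the usual half-point
# scheme): extend by L-1 on each side, full convolution, keep samples
# L, L+2, L+4, ... (1-based within the full convolution).
.dwt1_cols <- function(M, flt, mode) {
  N <- nrow(M)
  L <- flt$L
  if (mode == "symmetric") {
    out_len <- (N + L - 1L) %/% 2L
    # full conv index k (1-based) = L + 2*(i-1); conv[k] = sum_j h[j] ext[k-j+1]
    # ext index e (1-based) corresponds to original position e - (L-1)
    a <- matrix(0, out_len, ncol(M))
    d <- a
    pos0 <- L + 1L + 2L * (seq_len(out_len) - 1L)   # k for each output i
    for (j in seq_len(L)) {
      e <- pos0 - j + 1L                        # ext index
      src <- .reflect_idx(e - (L - 1L), N)      # original signal index
      a <- a + flt$dec_lo[j] * M[src, , drop = FALSE]
      d <- d + flt$dec_hi[j] * M[src, , drop = FALSE]
    }
  } else {                                      # periodization, even N
    if (N %% 2L != 0L)
      stop("periodization mode requires even subband sizes", call. = FALSE)
    out_len <- N %/% 2L
    a <- matrix(0, out_len, ncol(M))
    d <- a
    for (j in seq_len(L)) {
      src <- ((2L * (seq_len(out_len) - 1L) + (j - 1L)) %% N) + 1L
      a <- a + flt$dec_lo[j] * M[src, , drop = FALSE]
      d <- d + flt$dec_hi[j] * M[src, , drop = FALSE]
    }
  }
  list(a = a, d = d)
}

# inverse of .dwt1_cols: reconstruct N rows from a, d
.idwt1_cols <- function(a, d, N, flt, mode) {
  L <- flt$L
  o <- nrow(a)
  if (mode == "symmetric") {
    # upsample (zeros between samples), full convolution with synthesis
    # filters, sum branches, crop L-2 leading samples.
    up_len <- 2L * o - 1L
    ua <- matrix(0, up_len, ncol(a)); ua[seq(1L, up_len, by = 2L), ] <- a
    ud <- matrix(0, up_len, ncol(d)); ud[seq(1L, up_len, by = 2L), ] <- d
    conv_len <- up_len + L - 1L
    out <- matrix(0, conv_len, ncol(a))
    padded_a <- rbind(ua, matrix(0, L - 1L, ncol(a)))
    padded_d <- rbind(ud, matrix(0, L - 1L, ncol(d)))
    for (j in seq_len(L)) {
      rows <- seq_len(conv_len) - j + 1L
      ok <- rows >= 1L
      out[ok, ] <- out[ok, , drop = FALSE] +
        flt$rec_lo[j] * padded_a[rows[ok], , drop = FALSE] +
        flt$rec_hi[j] * padded_d[rows[ok], , drop = FALSE]
    }
    out[(L - 2L) + seq_len(N), , drop = FALSE]
  } else {
    # orthogonal transform: synthesis is the transpose of analysis
    out <- matrix(0, N, ncol(a))
    for (j in seq_len(L)) {
      dst <- ((2L * (seq_len(o) - 1L) + (j - 1L)) %% N) + 1L
      # accumulate; dst indices are unique per j
      out[dst, ] <- out[dst, , drop = FALSE] +
        flt$rec_lo[L - j + 1L] * a +
        flt$rec_hi[L - j + 1L] * d
    }
    out
  }
}

# Decomposition plan: subband shapes per level for an H x W image.
# Level numbering: 1 = coarsest (holds the approximation), `levels` = finest.
.dwt2_plan <- function(shape, spec) {
  flt <- .wav_filters(spec$family)
  H <- shape[1]; W <- shape[2]
  dims <- vector("list", spec$levels)
  h <- H; w <- W
  for (lev in seq_len(spec$levels)) {      # walking fine -> coarse
    if (spec$boundary_mode == "symmetric") {
      h2 <- (h + flt$L - 1L) %/% 2L
      w2 <- (w + flt$L - 1L) %/% 2L
    } else {
      if (h %% 2L != 0L || w %% 2L != 0L)
        stop("periodization mode requires even subband sizes at every level",
             call. = FALSE)
      h2 <- h %/% 2L; w2 <- w %/% 2L
    }
    dims[[spec$levels - lev + 1L]] <- list(in_shape = c(h, w),
                                           out_shape = c(h2, w2))
    h <- h2; w <- w2
  }
  # flat ordering: level-major from the coarsest level; at the coarsest
  # level approx -> horiz -> vert -> diag, at finer levels horiz -> vert ->
  # diag; row-major within each subband.
  index <- vector("list", spec$levels * 4L)
  ii <- 1L
  total <- 0L
  for (lev in seq_len(spec$levels)) {
    os <- dims[[lev]]$out_shape
    sb <- if (lev == 1L) .subband_names else .subband_names[-1L]
    for (s in sb) {
      nb <- os[1] * os[2]
      index[[ii]] <- data.frame(
        level = lev, subband = s,
        row = rep(seq_len(os[1]) - 1L, each = os[2]),
        col = rep(seq_len(os[2]) - 1L, times = os[1]),
        stringsAsFactors = FALSE)
      total <- total + nb
      ii <- ii + 1L
    }
  }
  index <- do.call(rbind, index[!vapply(index, is.null, logical(1))])
  list(flt = flt, dims = dims, index = index, n_total = total, shape = shape)
}

# single-level 2-D step: rows then columns
.dwt2_step <- function(M, flt, mode) {
  r <- .dwt1_cols(t(M), flt, mode)            # filter along rows (x)
  aa <- .dwt1_cols(t(r$a), flt, mode)         # then along columns (y)
  dd <- .dwt1_cols(t(r$d), flt, mode)
  list(approx = aa$a, horiz = aa$d, vert = dd$a, diag = dd$d)
}

.idwt2_step <- function(approx, horiz, vert, diag, in_shape, flt, mode) {
  ra <- .idwt1_cols(approx, horiz, in_shape[1], flt, mode)  # columns back
  rd <- .idwt1_cols(vert, diag, in_shape[1], flt, mode)
  t(.idwt1_cols(t(ra), t(rd), in_shape[2], flt, mode))      # rows back
}

# full multi-level decomposition of one frame -> named list of subband
# matrices, coarsest first
.dwt2_subbands <- function(frame, plan, spec) {
  out <- vector("list", spec$levels)
  cur <- frame
  for (lev in seq(spec$levels, 1L)) {         # fine -> coarse
    s <- .dwt2_step(cur, plan$flt, spec$boundary_mode)
    out[[lev]] <- s
    cur <- s$approx
  }
  out
}

.idwt2_subbands <- function(subbands, plan, spec) {
  cur <- subbands[[1L]]$approx
  for (lev in seq_len(spec$levels)) {
    s <- subbands[[lev]]
    cur <- .idwt2_step(cur, s$horiz, s$vert, s$diag,
                       plan$dims[[lev]]$in_shape, plan$flt,
                       spec$boundary_mode)
  }
  cur
}

.flatten_subbands <- function(subbands, spec) {
  parts <- list()
  for (lev in seq_len(spec$levels)) {
    s <- subbands[[lev]]
    sb <- if (lev == 1L) .subband_names else .subband_names[-1L]
    for (nm in sb) parts[[length(parts) + 1L]] <- as.vector(t(s[[nm]]))
  }
  unlist(parts, use.names = FALSE)
}

.unflatten_coeffs <- function(flat, plan, spec) {
  subbands <- vector("list", spec$levels)
  pos <- 0L
  for (lev in seq_len(spec$levels)) {
    os <- plan$dims[[lev]]$out_shape
    nb <- os[1] * os[2]
    sb <- if (lev == 1L) .subband_names else .subband_names[-1L]
    s <- list()
    for (nm in sb) {
      s[[nm]] <- matrix(flat[pos + seq_len(nb)], nrow = os[1], byrow = TRUE)
      pos <- pos + nb
    }
    if (lev > 1L) s$approx <- NULL
    subbands[[lev]] <- s
  }
  subbands
}

#' Full 2-D DWT of a single frame
#'
#' Decomposes one grayscale frame into `levels` scales and returns every
#' coefficient as a flat vector together with the index map that addresses
#' each coefficient as (level, subband, row, col).  The flat ordering is
#' level-major starting at the coarsest level, subbands ordered
#' approx, horiz, vert, diag (the approximation exists only at the coarsest
#' level), row-major within a subband.  This ordering is the documented
#' tie-break for variance ranking.
#'
#' @param frame Numeric H x W matrix of intensities.
#' @param spec A [wavelet_spec()].
#' @return List with `coefficients` (numeric vector), `index` (data frame
#'   with columns level, subband, row, col; rows parallel to
#'   `coefficients`), and `shape` = `c(H, W)`.
#' @seealso [idwt2_frame()] for the inverse, [build_feature_table()] for the
#'   sequence-level table.
#' @export
dwt2_frame <- function(frame, spec) {
  frame <- as.matrix(frame)
  if (any(!is.finite(frame))) stop("frame contains non-finite intensities",
                                   call. = FALSE)
  .check_levels(dim(frame), spec)
  plan <- .dwt2_plan(dim(frame), spec)
  sb <- .dwt2_subbands(frame, plan, spec)
  list(coefficients = .flatten_subbands(sb, spec),
       index = plan$index, shape = dim(frame))
}

#' Inverse 2-D DWT from a flat coefficient vector
#'
#' @param coefficients Flat coefficient vector in [dwt2_frame()] order.
#' @param shape Target image shape `c(H, W)`.
#' @param spec The [wavelet_spec()] used for analysis.
#' @return Numeric H x W matrix.
#' @export
idwt2_frame <- function(coefficients, shape, spec) {
  .check_levels(shape, spec)
  plan <- .dwt2_plan(shape, spec)
  if (length(coefficients) != plan$n_total)
    stop(sprintf("expected %d coefficients, got %d", plan$n_total,
                 length(coefficients)), call. = FALSE)
  sb <- .unflatten_coeffs(coefficients, plan, spec)
  .idwt2_subbands(sb, plan, spec)
}

# coefficient matrix for a whole sequence: F x n_total
.sequence_coeff_matrix <- function(sequence, spec) {
  shape <- dim(sequence$frames)[1:2]
  .check_levels(shape, spec)
  plan <- .dwt2_plan(shape, spec)
  F_ <- dim(sequence$frames)[3]
  out <- matrix(0, F_, plan$n_total)
  for (f in seq_len(F_)) {
    sb <- .dwt2_subbands(sequence$frames[, , f], plan, spec)
    out[f, ] <- .flatten_subbands(sb, spec)
  }
  list(values = out, plan = plan)
}

#' Rank wavelet coefficient positions by variance across frames
#'
#' Computes, for every coefficient position of the multi-level 2-D DWT, the
#' variance of that coefficient across the frames of the sequence
#' (denominator F - 1) and returns positions in descending variance order.
#' Ties are broken by the documented flat coefficient ordering, so the
#' ranking is deterministic.
#'
#' @param sequence An [image_sequence()].
#' @param spec A [wavelet_spec()].
#' @param exclude_approx If `TRUE`, approximation-subband positions are
#'   removed from the ranking (they carry mean brightness rather than
#'   motion-induced variation).  Default `FALSE`.
#' @return Data frame with columns level, subband, row, col, variance and
#'   flat_index (position in the flat coefficient vector), ordered by
#'   decreasing variance.
#' @export
rank_coefficients_by_variance <- function(sequence, spec,
                                          exclude_approx = FALSE) {
  stopifnot(inherits(sequence, "image_sequence"))
  if (dim(sequence$frames)[3] < 2L)
    stop("variance ranking needs at least 2 frames", call. = FALSE)
  cm <- .sequence_coeff_matrix(sequence, spec)
  v <- apply(cm$values, 2L, stats::var)
  idx <- cm$plan$index
  idx$variance <- v
  idx$flat_index <- seq_len(nrow(idx))
  if (exclude_approx) idx <- idx[idx$subband != "approx", , drop = FALSE]
  # stable sort: order() in R is stable, flat order is the tie-break
  idx[order(-idx$variance), , drop = FALSE]
}

#' Build the congruent two-way feature table
#'
#' Transforms every frame with the 2-D DWT and keeps the `n` coefficient
#' positions with the highest variance across frames, assembling the F x n
#' two-way table (rows = frames, columns = selected coefficients in rank
#' order).  If `n` is `NULL`, the smallest n whose columns carry at least
#' `variance_fraction` of the total coefficient variance is used, capped at
#' `max_n`.  No centering is applied at this stage.
#'
#' @param sequence An [image_sequence()].
#' @param spec A [wavelet_spec()].
#' @param n Number of coefficients to keep, or `NULL` for the variance
#'   fraction rule.
#' @param variance_fraction Target fraction of total variance when `n` is
#'   `NULL` (default 0.95).
#' @param max_n Cap on the automatic selection (default 10000).
#' @param exclude_approx Passed to [rank_coefficients_by_variance()].
#' @return Object of class `"maci_feature_table"`: list with `values`
#'   (F x n matrix), `index_map` (data frame level/subband/row/col/variance/
#'   flat_index), `image_shape`, `wavelet` (the spec), `frame_rate_hz`,
#'   `source_id`, and `column_means` (NULL until a model centers it).
#' @export
build_feature_table <- function(sequence, spec, n = NULL,
                                variance_fraction = 0.95, max_n = 10000L,
                                exclude_approx = FALSE) {
  stopifnot(inherits(sequence, "image_sequence"))
  cm <- .sequence_coeff_matrix(sequence, spec)
  v <- apply(cm$values, 2L, stats::var)
  idx <- cm$plan$index
  idx$variance <- v
  idx$flat_index <- seq_len(nrow(idx))
  if (exclude_approx) idx <- idx[idx$subband != "approx", , drop = FALSE]
  ord <- idx[order(-idx$variance), , drop = FALSE]
  if (is.null(n)) {
    cs <- cumsum(ord$variance)
    tot <- sum(ord$variance)
    n <- if (tot <= 0) 1L else which(cs >= variance_fraction * tot)[1L]
    n <- min(n, as.integer(max_n), nrow(ord))
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > nrow(ord))
    stop(sprintf("n must be between 1 and %d", nrow(ord)), call. = FALSE)
  sel <- ord[seq_len(n), , drop = FALSE]
  structure(list(values = cm$values[, sel$flat_index, drop = FALSE],
                 index_map = sel,
                 column_means = NULL,
                 image_shape = cm$plan$shape,
                 wavelet = spec,
                 frame_rate_hz = sequence$frame_rate_hz,
                 source_id = sequence$source_id),
            class = "maci_feature_table")
}

#' @export
print.maci_feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d frames x %d wavelet coefficients (%s, %d levels)\n",
              nrow(x$values), ncol(x$values), x$wavelet$family,
              x$wavelet$levels))
  cat(sprintf("  image %dx%d, source '%s'\n", x$image_shape[1],
              x$image_shape[2], x$source_id))
  invisible(x)
}

#' Back-project a loading vector into image space
#'
#' Places the `n` loading values at their coefficient positions in an
#' otherwise zero coefficient array and applies the inverse 2-D DWT, showing
#' which image regions drive a latent component.
#'
#' @param loading Numeric vector of length `ncol(table$values)`.
#' @param table A [build_feature_table()] result.
#' @return Numeric H x W matrix.
#' @export
loading_to_image <- function(loading, table) {
  stopifnot(inherits(table, "maci_feature_table"))
  if (length(loading) != ncol(table$values))
    stop(sprintf("loading has length %d but the table has %d columns",
                 length(loading), ncol(table$values)), call. = FALSE)
  plan <- .dwt2_plan(table$image_shape, table$wavelet)
  flat <- numeric(plan$n_total)
  flat[table$index_map$flat_index] <- loading
  idwt2_frame(flat, table$image_shape, table$wavelet)
}

# -- serialisation ------------------------------------------------------------

.coeff_label <- function(ix)
  sprintf("L%d:%s:%d:%d", ix$level, ix$subband, ix$row, ix$col)

#' Write / read a feature table as CSV plus JSON sidecar
#'
#' The CSV holds one row per frame with a header naming each column
#' `L{level}:{subband}:{row}:{col}`; the sidecar stores the wavelet spec,
#' image shape, frame rate and per-column variance so the table round-trips.
#'
#' @param table A `"maci_feature_table"`.
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "maci_feature_table"))
  df <- as.data.frame(table$values)
  names(df) <- .coeff_label(table$index_map)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(wavelet = unclass(table$wavelet),
               image_shape = as.integer(table$image_shape),
               frame_rate_hz = table$frame_rate_hz,
               source_id = table$source_id,
               flat_index = table$index_map$flat_index,
               variance = table$index_map$variance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path CSV path written by [write_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- names(df)
  parts <- regmatches(lab, regexec("^L([0-9]+):([a-z]+):([0-9]+):([0-9]+)$", lab))
  index_map <- data.frame(
    level = as.integer(vapply(parts, `[`, "", 2L)),
    subband = vapply(parts, `[`, "", 3L),
    row = as.integer(vapply(parts, `[`, "", 4L)),
    col = as.integer(vapply(parts, `[`, "", 5L)),
    variance = side$variance,
    flat_index = as.integer(side$flat_index),
    stringsAsFactors = FALSE)
  spec <- wavelet_spec(side$wavelet$family, side$wavelet$levels,
                       side$wavelet$boundary_mode)
  structure(list(values = as.matrix(df),
                 index_map = index_map,
                 column_means = NULL,
                 image_shape = as.integer(side$image_shape),
                 wavelet = spec,
                 frame_rate_hz = side$frame_rate_hz,
                 source_id = side$source_id),
            class = "maci_feature_table")
}
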