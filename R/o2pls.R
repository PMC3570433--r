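# Two-block O2PLS: joint, block-unique (orthogonal) and residual variation.
#
#   X = T P' + To Po' + E        Y = U C' + Uo Qo' + F
#
# Deterministic SVD formulation: the k joint weight pairs (W, C) are the
# leading singular triplets of Y' X; each block's orthogonal components are
# extracted OPLS-style from the residual of the block against its joint
# part, constrained to the orthocomplement of the joint weight space, and
# deflated.  Joint scores are recomputed on the orthogonally filtered
# blocks and linked by a per-component inner relation.
#
# All loadings/weights are stored at the full column dimension of the input
# blocks; columns dropped for zero variance carry zero loadings.

.as_block_matrix <- function(x) {
  if (inherits(x, "maci_feature_table")) x$values
  else as.matrix(x)
}

# numerical rank at relative singular value tolerance 1e-10
.num_rank <- function(d, tol = 1e-10) sum(d > d[1] * tol)

# fix sign: largest-magnitude element of each column positive
.sign_fix <- function(Wmat) {
  s <- apply(Wmat, 2L, function(w) {
    i <- which.max(abs(w))
    if (w[i] < 0) -1 else 1
  })
  s
}

# thin SVD; for wide matrices (n >> F, the feature-table case) it goes
# through the F x F Gram matrix, which is much cheaper than LAPACK on the
# full wide matrix and accurate for the dominant components used here
.thin_svd <- function(M) {
  F_ <- nrow(M); n <- ncol(M)
  if (n <= 3L * F_) return(svd(M))
  e <- eigen(tcrossprod(M), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  u <- e$vectors
  v <- crossprod(M, u)
  ok <- d > d[1] * 1e-12
  v[, ok] <- sweep(v[, ok, drop = FALSE], 2L, d[ok], `/`)
  v[, !ok] <- 0
  list(d = d, u = u, v = v)
}

# economy SVD of crossprod(Yc, Xc) without forming the n_y x n_x matrix:
# uses thin SVDs of the blocks (rank <= F), so cost scales with F^2 * n.
# Precomputed block SVDs may be passed in (cross-validation reuses them
# across candidate component counts).
.cross_svd <- function(Xc, Yc, k, sx = NULL, sy = NULL) {
  if (is.null(sx)) sx <- .thin_svd(Xc)
  if (is.null(sy)) sy <- .thin_svd(Yc)
  rx <- .num_rank(sx$d); ry <- .num_rank(sy$d)
  if (k > min(rx, ry))
    stop(sprintf("k = %d exceeds the achievable joint rank %d", k,
                 min(rx, ry)), call. = FALSE)
  K <- (sy$d[seq_len(ry)] * crossprod(sy$u[, seq_len(ry), drop = FALSE],
                                      sx$u[, seq_len(rx), drop = FALSE])) %*%
    diag(sx$d[seq_len(rx)], rx, rx)
  sk <- svd(K, nu = k, nv = k)
  list(C = sy$v[, seq_len(ry), drop = FALSE] %*% sk$u[, seq_len(k), drop = FALSE],
       W = sx$v[, seq_len(rx), drop = FALSE] %*% sk$v[, seq_len(k), drop = FALSE],
       d = sk$d, rank_x = rx, rank_y = ry)
}

# leading right singular vector via the F x F Gram matrix
.leading_right_sv <- function(M) {
  G <- tcrossprod(M)                       # F x F
  e <- eigen(G, symmetric = TRUE)
  lam <- max(e$values[1], 0)
  if (lam <= 0) return(NULL)
  u1 <- e$vectors[, 1L]
  v <- as.vector(crossprod(M, u1))
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps * 1e3) return(NULL)
  v / nv
}

# extract `n_orth` orthogonal components from block Z given joint weights Wj
.extract_orthogonal <- function(Z, Wj, n_orth) {
  To <- NULL; Po <- NULL; Wo <- NULL
  Zw <- Z
  for (i in seq_len(n_orth)) {
    Tj <- Zw %*% Wj
    Pj <- crossprod(Zw, Tj) %*% solve(crossprod(Tj))
    Ej <- Zw - tcrossprod(Tj, Pj)
    Eperp <- Ej - (Ej %*% Wj) %*% t(Wj)
    w_o <- .leading_right_sv(Eperp)
    if (is.null(w_o))
      stop(sprintf("no variance left for orthogonal component %d", i),
           call. = FALSE)
    # re-orthogonalise against the joint weight space (guards fp drift)
    w_o <- w_o - Wj %*% crossprod(Wj, w_o)
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- Zw %*% w_o
    p_o <- crossprod(Zw, t_o) / sum(t_o^2)
    if (p_o[which.max(abs(p_o))] < 0) {     # sign convention on loadings
      p_o <- -p_o; t_o <- -t_o; w_o <- -w_o
    }
    Zw <- Zw - tcrossprod(t_o, p_o)
    To <- cbind(To, t_o); Po <- cbind(Po, p_o); Wo <- cbind(Wo, w_o)
  }
  list(To = To, Po = Po, Wo = Wo, Z_filtered = Zw)
}

#' Fit a two-block O2PLS model
#'
#' Decomposes two column-centered blocks, paired row-wise in time, into
#' joint covariation (`k` components), block-unique orthogonal variation
#' (`l` components in X, `m` in Y) and residuals:
#' `X = T P' + To Po' + E` and `Y = U C' + Uo Qo' + F`.
#'
#' The joint weights are the `k` leading singular triplets of `Y'X`, so the
#' fit is deterministic; orthogonal components are directions of maximal
#' residual variance within the orthocomplement of the joint weight space,
#' which makes their scores uncorrelated with every column of the other
#' block whenever `k` captures the full cross-covariance rank.
#'
#' @param X,Y Numeric matrices (or [build_feature_table()] objects) with
#'   equal row counts; rows are synchronised frames.
#' @param k Number of joint components (>= 1).
#' @param l,m Numbers of orthogonal components in X and Y (>= 0).
#' @param center Subtract column means (default `TRUE`; disable only for
#'   pre-centered input).
#' @param block_scaling If `TRUE`, each block is scaled to unit total
#'   variance before fitting (off by default: feature columns were already
#'   selected by variance).
#' @return Object of class `"o2pls"` with score/loading/weight matrices
#'   `Tmat`, `P`, `W`, `U`, `C`, `To`, `Po`, `Wo`, `Uo`, `Qo`, `Co`,
#'   residuals `E`, `Fres`, the centering vectors, inner-relation
#'   coefficients `B_t_u` (regression of U on T, per component) and
#'   `B_u_t`, component counts and bookkeeping.
#' @references Trygg, J. (2002) O2-PLS for qualitative and quantitative
#'   analysis in multivariate calibration. Journal of Chemometrics 16,
#'   283-293.
#' @export
fit_o2pls <- function(X, Y, k, l = 0L, m = 0L, center = TRUE,
                      block_scaling = FALSE) {
  prep <- .o2pls_prep(X, Y, center, block_scaling)
  .fit_o2pls_prepped(prep, k, l, m)
}

# centering, zero-variance column handling, optional block scaling and the
# two block SVDs -- everything that does not depend on (k, l, m)
.o2pls_prep <- function(X, Y, center, block_scaling) {
  X <- .as_block_matrix(X); Y <- .as_block_matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (synchronise the sequences first)",
         call. = FALSE)
  mx <- if (center) colMeans(X) else numeric(ncol(X))
  my <- if (center) colMeans(Y) else numeric(ncol(Y))
  Xc_full <- sweep(X, 2L, mx)
  Yc_full <- sweep(Y, 2L, my)
  # drop zero-variance (all-zero after centering) columns
  keep_x <- which(colSums(Xc_full^2) > 0)
  keep_y <- which(colSums(Yc_full^2) > 0)
  if (length(keep_x) < ncol(X) || length(keep_y) < ncol(Y))
    warning(sprintf("dropping %d zero-variance column(s) in X, %d in Y",
                    ncol(X) - length(keep_x), ncol(Y) - length(keep_y)))
  Xc <- Xc_full[, keep_x, drop = FALSE]
  Yc <- Yc_full[, keep_y, drop = FALSE]
  scale_x <- if (block_scaling) sqrt(sum(Xc^2)) else 1
  scale_y <- if (block_scaling) sqrt(sum(Yc^2)) else 1
  if (block_scaling) { Xc <- Xc / scale_x; Yc <- Yc / scale_y }
  list(Xc = Xc, Yc = Yc, sx = .thin_svd(Xc), sy = .thin_svd(Yc),
       mx = mx, my = my, keep_x = keep_x, keep_y = keep_y,
       scale_x = scale_x, scale_y = scale_y,
       dim_x = ncol(X), dim_y = ncol(Y), n_obs = nrow(X),
       center = center, block_scaling = block_scaling)
}

.fit_o2pls_prepped <- function(prep, k, l, m) {
  k <- as.integer(k); l <- as.integer(l); m <- as.integer(m)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (l < 0L || m < 0L) stop("l and m must be >= 0", call. = FALSE)
  Xc <- prep$Xc; Yc <- prep$Yc
  keep_x <- prep$keep_x; keep_y <- prep$keep_y
  mx <- prep$mx; my <- prep$my

  cs <- .cross_svd(Xc, Yc, k, sx = prep$sx, sy = prep$sy)
  if (k + l > cs$rank_x)
    stop(sprintf("k + l = %d exceeds rank(X) = %d; at most l = %d orthogonal X components are identifiable",
                 k + l, cs$rank_x, max(0L, cs$rank_x - k)), call. = FALSE)
  if (k + m > cs$rank_y)
    stop(sprintf("k + m = %d exceeds rank(Y) = %d; at most m = %d orthogonal Y components are identifiable",
                 k + m, cs$rank_y, max(0L, cs$rank_y - k)), call. = FALSE)
  W <- cs$W; C <- cs$C
  # sign convention: largest |element| of each X-weight column positive;
  # the paired Y-weight column flips with it, preserving the positive
  # cross-covariance the singular pairs come with, so joint score pairs
  # correlate positively
  sw <- .sign_fix(W)
  W <- sweep(W, 2L, sw, `*`)
  C <- sweep(C, 2L, sw, `*`)

  ox <- .extract_orthogonal(Xc, W, l)
  oy <- .extract_orthogonal(Yc, C, m)
  Xf <- ox$Z_filtered
  Yf <- oy$Z_filtered

  Tmat <- Xf %*% W
  U <- Yf %*% C
  P <- crossprod(Xf, Tmat) %*% solve(crossprod(Tmat))
  E <- Xf - tcrossprod(Tmat, P)
  Fres <- Yf - tcrossprod(U, C)

  B_t_u <- colSums(Tmat * U) / colSums(Tmat^2)
  B_u_t <- colSums(Tmat * U) / colSums(U^2)

  embed <- function(M, keep, n) {
    if (is.null(M)) return(matrix(0, n, 0L))
    out <- matrix(0, n, ncol(M)); out[keep, ] <- M; out
  }
  structure(list(
    Tmat = Tmat, U = U,
    W = embed(W, keep_x, prep$dim_x), C = embed(C, keep_y, prep$dim_y),
    P = embed(P, keep_x, prep$dim_x),
    To = if (is.null(ox$To)) matrix(0, prep$n_obs, 0L) else ox$To,
    Po = embed(ox$Po, keep_x, prep$dim_x),
    Wo = embed(ox$Wo, keep_x, prep$dim_x),
    Uo = if (is.null(oy$To)) matrix(0, prep$n_obs, 0L) else oy$To,
    Qo = embed(oy$Po, keep_y, prep$dim_y),
    Co = embed(oy$Wo, keep_y, prep$dim_y),
    E = E, Fres = Fres,
    column_means_x = mx, column_means_y = my,
    keep_x = keep_x, keep_y = keep_y,
    scale_x = prep$scale_x, scale_y = prep$scale_y,
    k = k, l = l, m = m,
    B_t_u = B_t_u, B_u_t = B_u_t,
    singular_values = cs$d[seq_len(k)],
    center = prep$center, block_scaling = prep$block_scaling,
    dim_x = prep$dim_x, dim_y = prep$dim_y, n_obs = prep$n_obs),
    class = "o2pls")
}

#' @export
print.o2pls <- function(x, ...) {
  cat(sprintf("O2PLS model: %d joint, %d X-orthogonal, %d Y-orthogonal component(s)\n",
              x$k, x$l, x$m))
  cat(sprintf("  %d paired observations; X: %d columns, Y: %d columns\n",
              x$n_obs, x$dim_x, x$dim_y))
  rc <- score_correlations(x)
  cat("  joint score correlations:",
      paste(sprintf("%.3f", rc), collapse = ", "), "\n")
  invisible(x)
}

#' Explained-variance report
#'
#' Fractions of each centered block's total sum of squares captured by the
#' joint part, the orthogonal part and the residual.  The three parts are
#' mutually orthogonal by construction, so the fractions sum to one.
#'
#' @param model A fitted [fit_o2pls()] model.
#' @param X,Y The blocks the model was fitted on.
#' @return List of class `"o2pls_variance"` with fields `r2x_joint`,
#'   `r2x_orth`, `r2x_resid`, `r2y_joint`, `r2y_orth`, `r2y_resid` and a
#'   `per_component` data frame.
#' @export
explained_variance <- function(model, X, Y) {
  stopifnot(inherits(model, "o2pls"))
  X <- .as_block_matrix(X); Y <- .as_block_matrix(Y)
  if (ncol(X) != model$dim_x || ncol(Y) != model$dim_y ||
      nrow(X) != model$n_obs || nrow(Y) != model$n_obs)
    stop("block shapes do not match the fitted model", call. = FALSE)
  Xc <- sweep(X, 2L, model$column_means_x)[, model$keep_x, drop = FALSE] /
    model$scale_x
  Yc <- sweep(Y, 2L, model$column_means_y)[, model$keep_y, drop = FALSE] /
    model$scale_y
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  P <- model$P[model$keep_x, , drop = FALSE]
  Po <- model$Po[model$keep_x, , drop = FALSE]
  C <- model$C[model$keep_y, , drop = FALSE]
  Qo <- model$Qo[model$keep_y, , drop = FALSE]
  ss_joint_x <- sum(tcrossprod(model$Tmat, P)^2)
  ss_orth_x <- if (model$l > 0) sum(tcrossprod(model$To, Po)^2) else 0
  ss_joint_y <- sum(tcrossprod(model$U, C)^2)
  ss_orth_y <- if (model$m > 0) sum(tcrossprod(model$Uo, Qo)^2) else 0
  per <- data.frame(
    component = seq_len(model$k),
    r2x = colSums(model$Tmat^2) * colSums(P^2) / ssx,
    r2y = colSums(model$U^2) * colSums(C^2) / ssy)
  structure(list(
    r2x_joint = ss_joint_x / ssx, r2x_orth = ss_orth_x / ssx,
    r2x_resid = sum(model$E^2) / ssx,
    r2y_joint = ss_joint_y / ssy, r2y_orth = ss_orth_y / ssy,
    r2y_resid = sum(model$Fres^2) / ssy,
    per_component = per), class = "o2pls_variance")
}

#' @export
print.o2pls_variance <- function(x, ...) {
  cat(sprintf("X: joint %.1f%%, orthogonal %.1f%%, residual %.1f%%\n",
              100 * x$r2x_joint, 100 * x$r2x_orth, 100 * x$r2x_resid))
  cat(sprintf("Y: joint %.1f%%, orthogonal %.1f%%, residual %.1f%%\n",
              100 * x$r2y_joint, 100 * x$r2y_orth, 100 * x$r2y_resid))
  invisible(x)
}

#' Per-component joint score correlations
#'
#' Pearson correlation between paired joint score columns `T_i` and `U_i`;
#' high values mean the two captures share the corresponding latent
#' dynamic.  Zero-variance score columns yield 0 with a warning.
#'
#' @param model A fitted [fit_o2pls()] model.
#' @return Numeric vector of length `k`.
#' @export
score_correlations <- function(model) {
  stopifnot(inherits(model, "o2pls"))
  vapply(seq_len(model$k), function(i) {
    t_i <- model$Tmat[, i]; u_i <- model$U[, i]
    if (stats::sd(t_i) == 0 || stats::sd(u_i) == 0) {
      warning(sprintf("joint component %d has a zero-variance score column", i))
      return(0)
    }
    stats::cor(t_i, u_i)
  }, numeric(1))
}

# shared deflate-and-project: returns filtered centered new data
.filter_new <- function(Z_new, means, keep, scale, Wo, Po, n_orth) {
  Zc <- sweep(Z_new, 2L, means)[, keep, drop = FALSE] / scale
  for (i in seq_len(n_orth)) {
    t_o <- Zc %*% Wo[, i, drop = FALSE]
    Zc <- Zc - tcrossprod(t_o, Po[, i, drop = FALSE])
  }
  Zc
}

#' Predict Y from new X observations (and X from Y)
#'
#' Centers the new rows with the stored means, strips the X-orthogonal
#' variation, projects onto the joint weights, maps through the inner
#' relation and reconstructs on the Y loadings.
#'
#' @param model A fitted [fit_o2pls()] model.
#' @param X_new Matrix with `dim_x` columns.
#' @return Matrix of predicted Y rows (original scale).
#' @export
predict_y <- function(model, X_new) {
  stopifnot(inherits(model, "o2pls"))
  X_new <- .as_block_matrix(X_new)
  if (ncol(X_new) != model$dim_x)
    stop(sprintf("X_new has %d columns; the model expects %d", ncol(X_new),
                 model$dim_x), call. = FALSE)
  Xc <- .filter_new(X_new, model$column_means_x, model$keep_x, model$scale_x,
                    model$Wo[model$keep_x, , drop = FALSE],
                    model$Po[model$keep_x, , drop = FALSE], model$l)
  T_new <- Xc %*% model$W[model$keep_x, , drop = FALSE]
  U_hat <- sweep(T_new, 2L, model$B_t_u, `*`)
  Yc_hat <- tcrossprod(U_hat, model$C[model$keep_y, , drop = FALSE]) *
    model$scale_y
  out <- matrix(rep(model$column_means_y, each = nrow(X_new)),
                nrow(X_new), model$dim_y)
  out[, model$keep_y] <- out[, model$keep_y] + Yc_hat
  out
}

#' @rdname predict_y
#' @param Y_new Matrix with `dim_y` columns.
#' @export
predict_x <- function(model, Y_new) {
  stopifnot(inherits(model, "o2pls"))
  Y_new <- .as_block_matrix(Y_new)
  if (ncol(Y_new) != model$dim_y)
    stop(sprintf("Y_new has %d columns; the model expects %d", ncol(Y_new),
                 model$dim_y), call. = FALSE)
  Yc <- .filter_new(Y_new, model$column_means_y, model$keep_y, model$scale_y,
                    model$Co[model$keep_y, , drop = FALSE],
                    model$Qo[model$keep_y, , drop = FALSE], model$m)
  U_new <- Yc %*% model$C[model$keep_y, , drop = FALSE]
  T_hat <- sweep(U_new, 2L, model$B_u_t, `*`)
  Xc_hat <- tcrossprod(T_hat, model$P[model$keep_x, , drop = FALSE]) *
    model$scale_x
  out <- matrix(rep(model$column_means_x, each = nrow(Y_new)),
                nrow(Y_new), model$dim_x)
  out[, model$keep_x] <- out[, model$keep_x] + Xc_hat
  out
}

#' Cross-validated component selection
#'
#' Chooses the numbers of joint (`k`), X-orthogonal (`l`) and Y-orthogonal
#' (`m`) components by fold-out prediction.  Rows are split into `folds`
#' contiguous blocks (frames form a time series, so random folds would leak
#' temporal autocorrelation).  For each candidate the model is fitted on
#' the remaining rows and the held-out rows of each block are predicted
#' from the other block through the joint part;
#' `Q2 = 1 - PRESS / SS` is accumulated over folds.  Components are added
#' greedily -- joint first, then X-orthogonal, then Y-orthogonal.  A joint
#' component is accepted while Q2Y improves by more than `threshold`.  An
#' orthogonal component is block-internal structure, so it is judged by
#' two conditions: (a) it must be real structure within its own block --
#' its reconstruction Q2 of the joint-filtered residual, cross-validated
#' with interleaved (venetian-blind) folds so that temporally local events
#' appear in every fold and reported in excess of the isotropic 1/n
#' baseline, must exceed `threshold` (Wold-style eigenvector
#' cross-validation); and (b) it must be block-unique in majority: less
#' than half of its held-out score variance may be predictable from the
#' other block's joint-filtered residual, which rejects shared leftover
#' structure that merely fell below the joint threshold while tolerating
#' minor cross-contamination of a genuinely unique event.  If no
#' joint component passes, `k = 0` is returned with the
#' `no_joint_variation` flag.
#'
#' @param X,Y Blocks as in [fit_o2pls()].
#' @param max_k,max_l,max_m Largest candidate counts.
#' @param folds Number of contiguous folds (default 7).
#' @param threshold Minimum Q2 improvement to accept a component
#'   (default 0.01).
#' @param center,block_scaling Passed to [fit_o2pls()].
#' @return Object of class `"o2pls_cv"`: `selected` (named vector k, l, m),
#'   `no_joint_variation` flag, `grid` (data frame of candidate counts with
#'   Q2X/Q2Y) and `rule_trace` (character log of accept/reject decisions).
#' @export
cross_validate <- function(X, Y, max_k = 5L, max_l = 3L, max_m = 3L,
                           folds = 7L, threshold = 0.01, center = TRUE,
                           block_scaling = FALSE) {
  X <- .as_block_matrix(X); Y <- .as_block_matrix(Y)
  folds <- as.integer(folds)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows",
                         call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  fold_id <- rep(seq_len(folds), diff(floor(seq(0, n, length.out = folds + 1))))

  # per-fold preparation (centering + block SVDs) is independent of the
  # candidate component counts, so it is computed once and reused
  fold_prep <- lapply(seq_len(folds), function(fo) {
    ho <- fold_id == fo
    list(ho = ho,
         prep = .o2pls_prep(X[!ho, , drop = FALSE], Y[!ho, , drop = FALSE],
                            center, block_scaling))
  })

  q2_pair <- function(k, l, m) {
    press_y <- 0; ss_y <- 0; press_x <- 0; ss_x <- 0
    for (fo in seq_len(folds)) {
      ho <- fold_prep[[fo]]$ho
      Xho <- X[ho, , drop = FALSE]; Yho <- Y[ho, , drop = FALSE]
      Xtr <- X[!ho, , drop = FALSE]; Ytr <- Y[!ho, , drop = FALSE]
      if (k == 0L) {
        Yhat <- matrix(rep(colMeans(Ytr), each = sum(ho)), sum(ho), ncol(Y))
        Xhat <- matrix(rep(colMeans(Xtr), each = sum(ho)), sum(ho), ncol(X))
      } else {
        fit <- .fit_o2pls_prepped(fold_prep[[fo]]$prep, k, l, m)
        Yhat <- predict_y(fit, Xho)
        Xhat <- predict_x(fit, Yho)
      }
      my_tr <- colMeans(Ytr); mx_tr <- colMeans(Xtr)
      press_y <- press_y + sum((Yho - Yhat)^2)
      ss_y <- ss_y + sum(sweep(Yho, 2L, my_tr)^2)
      press_x <- press_x + sum((Xho - Xhat)^2)
      ss_x <- ss_x + sum(sweep(Xho, 2L, mx_tr)^2)
    }
    c(q2x = 1 - press_x / ss_x, q2y = 1 - press_y / ss_y)
  }

  # interleaved folds for the orthogonal-component reconstruction CV
  # (a temporally local event must appear in every training fold)
  fold_prep_int <- NULL
  get_int_prep <- function() {
    if (is.null(fold_prep_int))
      fold_prep_int <<- lapply(seq_len(folds), function(fo) {
        ho <- rep_len(seq_len(folds), n) == fo
        list(ho = ho,
             prep = .o2pls_prep(X[!ho, , drop = FALSE],
                                Y[!ho, , drop = FALSE],
                                center, block_scaling))
      })
    fold_prep_int
  }

  # cross-validated tests of the newest orthogonal component of one block
  # (interleaved folds): (a) reconstruction Q2 of the held-out
  # joint-filtered residual, in excess of the isotropic 1/n baseline --
  # is it real structure?  (b) predictability of its held-out scores from
  # the other block's residual -- is it really unrelated?
  q2_orth <- function(k, l, m, side) {
    fp <- get_int_prep()
    press <- 0; ss <- 0; base_dim <- 0
    press_rel <- 0; ss_rel <- 0
    for (fo in seq_len(folds)) {
      ho <- fp[[fo]]$ho
      fit <- .fit_o2pls_prepped(fp[[fo]]$prep, k, l, m)
      if (side == "x") {
        kc <- fit$keep_x
        Zc <- sweep(X[ho, , drop = FALSE], 2L,
                    fit$column_means_x)[, kc, drop = FALSE] / fit$scale_x
        Wo <- fit$Wo[kc, , drop = FALSE]; Po <- fit$Po[kc, , drop = FALSE]
        n_o <- fit$l
        Wj <- fit$W[kc, , drop = FALSE]; Pj <- fit$P[kc, , drop = FALSE]
        sco_tr <- fit$To; Res_tr <- fit$Fres
        oc <- fit$keep_y
        Ocf <- .filter_new(Y[ho, , drop = FALSE], fit$column_means_y, oc,
                           fit$scale_y, fit$Co[oc, , drop = FALSE],
                           fit$Qo[oc, , drop = FALSE], fit$m)
        Cj <- fit$C[oc, , drop = FALSE]
        Cj_load <- Cj                      # C is weights and loadings
      } else {
        kc <- fit$keep_y
        Zc <- sweep(Y[ho, , drop = FALSE], 2L,
                    fit$column_means_y)[, kc, drop = FALSE] / fit$scale_y
        Wo <- fit$Co[kc, , drop = FALSE]; Po <- fit$Qo[kc, , drop = FALSE]
        n_o <- fit$m
        Wj <- fit$C[kc, , drop = FALSE]; Pj <- fit$C[kc, , drop = FALSE]
        sco_tr <- fit$Uo; Res_tr <- fit$E
        oc <- fit$keep_x
        Ocf <- .filter_new(X[ho, , drop = FALSE], fit$column_means_x, oc,
                           fit$scale_x, fit$Wo[oc, , drop = FALSE],
                           fit$Po[oc, , drop = FALSE], fit$l)
        Cj <- fit$W[oc, , drop = FALSE]
        Cj_load <- fit$P[oc, , drop = FALSE]
      }
      for (i in seq_len(n_o - 1L))
        Zc <- Zc - tcrossprod(Zc %*% Wo[, i, drop = FALSE],
                              Po[, i, drop = FALSE])
      Tj <- Zc %*% Wj
      Ej <- Zc - tcrossprod(Tj, Pj)
      Ep <- Ej - (Ej %*% Wj) %*% t(Wj)
      t_o_ho <- Ep %*% Wo[, n_o, drop = FALSE]
      rec <- tcrossprod(t_o_ho, Po[, n_o, drop = FALSE])
      press <- press + sum((Ep - rec)^2)
      ss <- ss + sum(Ep^2)
      base_dim <- base_dim + ncol(Ep)
      # relatedness: regress the candidate's training scores on the best-
      # matching residual direction of the other block, then predict the
      # held-out scores
      t_o_tr <- sco_tr[, n_o]
      c_rel <- crossprod(Res_tr, t_o_tr)
      nrm <- sqrt(sum(c_rel^2))
      if (nrm > 0) {
        c_rel <- c_rel / nrm
        u_tr <- Res_tr %*% c_rel
        b_rel <- sum(t_o_tr * u_tr) / sum(u_tr^2)
        Res_ho <- Ocf - tcrossprod(Ocf %*% Cj, Cj_load)
        u_ho <- Res_ho %*% c_rel
        press_rel <- press_rel + sum((t_o_ho - b_rel * u_ho)^2)
      } else press_rel <- press_rel + sum(t_o_ho^2)
      ss_rel <- ss_rel + sum(t_o_ho^2)
    }
    list(excess = (1 - press / ss) - folds / base_dim,
         relatedness = 1 - press_rel / ss_rel)
  }

  grid <- data.frame(k = integer(0), l = integer(0), m = integer(0),
                     q2x = numeric(0), q2y = numeric(0), q2_orth = numeric(0))
  trace <- character(0)
  note <- function(fmt, ...) trace <<- c(trace, sprintf(fmt, ...))
  eval_cand <- function(k, l, m, q2o = NA_real_) {
    q <- tryCatch(q2_pair(k, l, m), error = function(e) {
      note("candidate (k=%d, l=%d, m=%d) infeasible: %s", k, l, m,
           conditionMessage(e))
      NULL
    })
    if (!is.null(q))
      grid <<- rbind(grid, data.frame(k = k, l = l, m = m,
                                      q2x = q[["q2x"]], q2y = q[["q2y"]],
                                      q2_orth = q2o))
    q
  }

  # joint components
  best <- c(q2x = 0, q2y = 0)
  k_sel <- 0L
  for (kk in seq_len(max_k)) {
    q <- eval_cand(kk, 0L, 0L)
    if (is.null(q)) break
    if (q[["q2y"]] > best[["q2y"]] + threshold) {
      note("accept k=%d: Q2Y %.4f -> %.4f", kk, best[["q2y"]], q[["q2y"]])
      best <- q; k_sel <- kk
    } else {
      note("reject k=%d: Q2Y %.4f (best %.4f, threshold %.3f)", kk,
           q[["q2y"]], best[["q2y"]], threshold)
      break
    }
  }
  if (k_sel == 0L) {
    note("no significant joint variation: k = 0")
    return(structure(list(selected = c(k = 0L, l = 0L, m = 0L),
                          no_joint_variation = TRUE, folds = folds,
                          threshold = threshold, grid = grid,
                          rule_trace = trace), class = "o2pls_cv"))
  }
  # orthogonal components: real residual structure within the block
  # (excess reconstruction Q2 over threshold) whose scores are not
  # predictable from the other block (relatedness Q2 at or below it)
  l_sel <- 0L
  for (ll in seq_len(max_l)) {
    qo <- tryCatch(q2_orth(k_sel, ll, 0L, "x"), error = function(e) {
      note("orthogonal candidate l=%d infeasible: %s", ll,
           conditionMessage(e))
      NULL
    })
    if (is.null(qo)) break
    q <- eval_cand(k_sel, ll, 0L, q2o = qo$excess)
    if (is.null(q)) break
    if (qo$excess > threshold && qo$relatedness < 0.5) {
      note("accept l=%d: residual Q2 excess %.4f, relatedness %.4f", ll,
           qo$excess, qo$relatedness)
      best <- q; l_sel <- ll
    } else {
      note("reject l=%d: residual Q2 excess %.4f (threshold %.3f), relatedness %.4f",
           ll, qo$excess, threshold, qo$relatedness)
      break
    }
  }
  # Y-orthogonal components, symmetrically
  m_sel <- 0L
  for (mm in seq_len(max_m)) {
    qo <- tryCatch(q2_orth(k_sel, l_sel, mm, "y"), error = function(e) {
      note("orthogonal candidate m=%d infeasible: %s", mm,
           conditionMessage(e))
      NULL
    })
    if (is.null(qo)) break
    q <- eval_cand(k_sel, l_sel, mm, q2o = qo$excess)
    if (is.null(q)) break
    if (qo$excess > threshold && qo$relatedness < 0.5) {
      note("accept m=%d: residual Q2 excess %.4f, relatedness %.4f", mm,
           qo$excess, qo$relatedness)
      best <- q; m_sel <- mm
    } else {
      note("reject m=%d: residual Q2 excess %.4f (threshold %.3f), relatedness %.4f",
           mm, qo$excess, threshold, qo$relatedness)
      break
    }
  }
  structure(list(selected = c(k = k_sel, l = l_sel, m = m_sel),
                 no_joint_variation = FALSE, folds = folds,
                 threshold = threshold, grid = grid, rule_trace = trace),
            class = "o2pls_cv")
}

#' @export
print.o2pls_cv <- function(x, ...) {
  s <- x$selected
  cat(sprintf("O2PLS cross-validation (%d folds, threshold %.3f): k=%d, l=%d, m=%d%s\n",
              x$folds, x$threshold, s["k"], s["l"], s["m"],
              if (x$no_joint_variation) " [no significant joint variation]"
              else ""))
  invisible(x)
}

# -- serialisation ------------------------------------------------------------

#' Save / load an O2PLS model as a directory of CSV files
#'
#' One CSV per matrix plus `model.json` for the scalars and centering
#' vectors; round-trips exactly (full double precision).
#'
#' @param model A fitted `"o2pls"` model.
#' @param dir Target directory (created if missing).
#' @return `dir` (writer) / the model (reader), invisibly.
#' @export
write_o2pls <- function(model, dir) {
  stopifnot(inherits(model, "o2pls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- c("Tmat", "U", "W", "C", "P", "To", "Po", "Wo", "Uo", "Qo", "Co",
            "E", "Fres")
  for (nm in mats) {
    utils::write.csv(format(as.data.frame(model[[nm]]), digits = 17),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  scal <- model[c("column_means_x", "column_means_y", "keep_x", "keep_y",
                  "scale_x", "scale_y", "k", "l", "m", "B_t_u", "B_u_t",
                  "singular_values", "center", "block_scaling", "dim_x",
                  "dim_y", "n_obs")]
  jsonlite::write_json(scal, file.path(dir, "model.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_o2pls
#' @export
read_o2pls <- function(dir) {
  scal <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  row_of <- c(Tmat = "n_obs", U = "n_obs", To = "n_obs", Uo = "n_obs",
              E = "n_obs", Fres = "n_obs", W = "dim_x", P = "dim_x",
              Po = "dim_x", Wo = "dim_x", C = "dim_y", Qo = "dim_y",
              Co = "dim_y")
  model <- list()
  for (nm in names(row_of)) {
    df <- tryCatch(utils::read.csv(file.path(dir, paste0(nm, ".csv"))),
                   error = function(e) NULL)
    M <- if (is.null(df) || ncol(df) == 0L)
      matrix(0, scal[[row_of[[nm]]]], 0L)      # an empty component set
    else as.matrix(df)
    dimnames(M) <- NULL
    model[[nm]] <- M
  }
  for (nm in names(scal)) model[[nm]] <- scal[[nm]]
  for (nm in c("k", "l", "m", "keep_x", "keep_y", "dim_x", "dim_y", "n_obs"))
    model[[nm]] <- as.integer(model[[nm]])
  structure(model, class = "o2pls")
}

#' Export joint and orthogonal scores as a tidy CSV
#'
#' One row per (frame, component, block, kind) with the score value and
#' the frame time -- the substrate for score-vs-time plots.
#'
#' @param model A fitted `"o2pls"` model.
#' @param frame_rate_hz Frame rate used to derive `time_s`.
#' @param path Optional CSV output path.
#' @return The tidy data frame (invisibly if `path` is given).
#' @export
export_scores <- function(model, frame_rate_hz = 78.6, path = NULL) {
  stopifnot(inherits(model, "o2pls"))
  tidy_block <- function(S, block, kind) {
    if (ncol(S) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(ncol(S)), function(i)
      data.frame(frame_index = seq_len(nrow(S)),
                 time_s = (seq_len(nrow(S)) - 1L) / frame_rate_hz,
                 component = i, block = block, kind = kind,
                 value = S[, i])))
  }
  df <- rbind(tidy_block(model$Tmat, "X", "joint"),
              tidy_block(model$U, "Y", "joint"),
              tidy_block(model$To, "X", "orthogonal"),
              tidy_block(model$Uo, "Y", "orthogonal"))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
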