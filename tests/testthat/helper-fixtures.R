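# Shared fixtures: tiny deterministic sequences, constructed O2PLS blocks
# with known factors, and independently coded oracles.

# small random sequence (speckle-free white texture is enough for most
# wavelet/tracking unit tests)
random_sequence <- function(F = 6L, H = 32L, W = 32L, seed = 1L,
                            frame_rate_hz = 78.6) {
  set.seed(seed)
  image_sequence(array(runif(H * W * F, 0, 255), c(H, W, F)),
                 frame_rate_hz = frame_rate_hz, source_id = "fixture")
}

# mean-center a vector
ctr <- function(v) v - mean(v)

# draw one element of v (avoids sample()'s scalar expansion)
pick1 <- function(v) v[sample.int(length(v), 1L)]

# orthogonalise b against a (both centered), return centered result
orth_to <- function(b, a) ctr(b - a * sum(a * b) / sum(a * a))

# exact-rank two-block construction: X = t p' + to po', Y = t q' (+ noise)
# with to _|_ t and po _|_ p; returns the factors for recovery checks
make_joint_blocks <- function(F = 100L, n_x = 40L, n_y = 30L, seed = 1L,
                              noise_frac = 0) {
  set.seed(seed)
  t_lat <- ctr(rnorm(F))
  to_lat <- orth_to(rnorm(F), t_lat)
  p <- rnorm(n_x)
  po <- rnorm(n_x); po <- po - p * sum(po * p) / sum(p^2)
  q <- rnorm(n_y)
  X <- t_lat %*% t(p) + to_lat %*% t(po)
  Y <- t_lat %*% t(q)
  if (noise_frac > 0) {
    sx <- sqrt(noise_frac * sum(X^2) / length(X))
    sy <- sqrt(noise_frac * sum(Y^2) / length(Y))
    X <- X + matrix(rnorm(length(X), 0, sx), nrow(X))
    Y <- Y + matrix(rnorm(length(Y), 0, sy), nrow(Y))
  }
  list(X = X, Y = Y, t = t_lat, to = to_lat, p = p, po = po, q = q)
}

# independently coded exhaustive block matcher: explicit loops over shifts
# and pixels, same tie rule (smallest epsilon, then shift length, then
# (dy, dx) lexicographic)
oracle_match_block <- function(frame_t, frame_t1, r, radius, weight = NULL) {
  H <- nrow(frame_t); W <- ncol(frame_t)
  best <- NULL
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (r$x0 + dx < 0 || r$y0 + dy < 0 ||
        r$x0 + dx + r$width > W || r$y0 + dy + r$height > H) next
    eps <- 0
    for (yy in seq_len(r$height)) for (xx in seq_len(r$width)) {
      a <- frame_t[r$y0 + yy, r$x0 + xx]
      b <- frame_t1[r$y0 + dy + yy, r$x0 + dx + xx]
      wgt <- if (is.null(weight)) 1 else weight[yy, xx]
      eps <- eps + (a - b)^2 * wgt
    }
    key <- c(eps, dx^2 + dy^2, dy, dx)
    if (is.null(best)) best <- list(dx = dx, dy = dy, eps = eps, key = key)
    else {
      for (j in 1:4) {
        if (key[j] < best$key[j]) {
          best <- list(dx = dx, dy = dy, eps = eps, key = key); break
        }
        if (key[j] > best$key[j]) break
      }
    }
  }
  best
}

# brute-force DWT analysis matrix: column j = transform of the j-th
# standard basis image (vec in row-major pixel order)
dwt_analysis_matrix <- function(H, W, spec) {
  n_out <- length(dwt2_frame(matrix(0, H, W), spec)$coefficients)
  A <- matrix(0, n_out, H * W)
  j <- 1L
  for (rr in seq_len(H)) for (cc in seq_len(W)) {
    e <- matrix(0, H, W); e[rr, cc] <- 1
    A[, j] <- dwt2_frame(e, spec)$coefficients
    j <- j + 1L
  }
  A
}
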