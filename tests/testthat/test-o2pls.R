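test_that("self-paired blocks recover the first principal component", {
  set.seed(8)
  X <- matrix(rnorm(80 * 15), 80, 15)
  mod <- fit_o2pls(X, X, k = 1L)
  expect_equal(score_correlations(mod), 1, tolerance = 1e-10)
  pc1 <- prcomp(X, center = TRUE, scale. = FALSE)$x[, 1]
  expect_equal(abs(cor(mod$Tmat[, 1], pc1)), 1, tolerance = 1e-8)
})

test_that("noiseless joint + orthogonal factors are recovered exactly", {
  blk <- make_joint_blocks(seed = 42)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L, m = 0L)
  expect_gte(abs(cor(mod$Tmat[, 1], blk$t)), 1 - 1e-6)
  expect_gte(abs(cor(mod$To[, 1], blk$to)), 1 - 1e-6)
  expect_lt(max(abs(mod$E)), 1e-8)
  expect_lt(max(abs(mod$Fres)), 1e-8)
  ev <- explained_variance(mod, blk$X, blk$Y)
  expect_equal(ev$r2x_resid, 0, tolerance = 1e-8)
  # principal angle between span(W) and the true joint weight direction
  w_true <- blk$p / sqrt(sum(blk$p^2))
  cosang <- abs(sum(mod$W[, 1] * w_true))
  expect_lt(acos(min(cosang, 1)), 1e-6)
})

test_that("joint latents survive 5% noise across seeded replicates", {
  for (seed in 1:20) {
    blk <- make_joint_blocks(seed = seed, noise_frac = 0.05)
    mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
    expect_gte(abs(cor(mod$Tmat[, 1], blk$t)), 0.99)
  }
})

test_that("model invariants hold on seeded structured datasets", {
  for (seed in 1:20) {
    set.seed(seed)
    F_ <- 60L; nx <- 25L; ny <- 18L
    t1 <- ctr(rnorm(F_)); t2 <- orth_to(rnorm(F_), t1)
    tox <- orth_to(orth_to(rnorm(F_), t1), t2)
    # the two block-unique latents must also be mutually orthogonal, or
    # they would create joint covariation of their own
    toy <- orth_to(orth_to(orth_to(rnorm(F_), t1), t2), tox)
    X <- t1 %*% t(rnorm(nx)) + t2 %*% t(rnorm(nx)) + tox %*% t(rnorm(nx))
    Y <- t1 %*% t(rnorm(ny)) + t2 %*% t(rnorm(ny)) + toy %*% t(rnorm(ny))
    mod <- fit_o2pls(X, Y, k = 2L, l = 1L, m = 1L)
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    # reconstruction identities
    expect_lt(max(abs(Xc - (tcrossprod(mod$Tmat, mod$P) +
                              tcrossprod(mod$To, mod$Po) + mod$E))), 1e-9)
    expect_lt(max(abs(Yc - (tcrossprod(mod$U, mod$C) +
                              tcrossprod(mod$Uo, mod$Qo) + mod$Fres))), 1e-9)
    # orthogonal scores uncorrelated with every column of the other block
    expect_lt(max(abs(cor(mod$To, Yc))), 1e-6)
    expect_lt(max(abs(cor(mod$Uo, Xc))), 1e-6)
    # orthonormal weights
    expect_lt(max(abs(crossprod(mod$W) - diag(2))), 1e-8)
    expect_lt(max(abs(crossprod(mod$C) - diag(2))), 1e-8)
    # variance fractions sum to one
    ev <- explained_variance(mod, X, Y)
    expect_equal(ev$r2x_joint + ev$r2x_orth + ev$r2x_resid, 1,
                 tolerance = 1e-6)
    expect_equal(ev$r2y_joint + ev$r2y_orth + ev$r2y_resid, 1,
                 tolerance = 1e-6)
    expect_true(all(unlist(ev[1:6]) >= -1e-12 & unlist(ev[1:6]) <= 1 + 1e-12))
  }
})

test_that("an l = m = 0 model reports exactly zero orthogonal variance", {
  blk <- make_joint_blocks(seed = 3, noise_frac = 0.05)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L)
  ev <- explained_variance(mod, blk$X, blk$Y)
  expect_identical(ev$r2x_orth, 0)
  expect_identical(ev$r2y_orth, 0)
})

test_that("signal at 4:1 SS ratio yields about 80% modelled variance", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 300)
    F_ <- 100L; nx <- 40L
    t1 <- ctr(rnorm(F_)); tox <- orth_to(rnorm(F_), t1)
    sig <- t1 %*% t(rnorm(nx)) + tox %*% t(rnorm(nx))
    noise <- matrix(rnorm(F_ * nx), F_)
    noise <- noise * sqrt(sum(sig^2) / 4 / sum(noise^2))
    X <- sig + noise
    Y <- t1 %*% t(rnorm(30L)) + 0.05 * matrix(rnorm(F_ * 30L), F_)
    mod <- fit_o2pls(X, Y, k = 1L, l = 1L)
    ev <- explained_variance(mod, X, Y)
    if (abs(ev$r2x_joint + ev$r2x_orth - 0.8) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("independent blocks give low score correlations; shared latents high", {
  # null bound derived by simulation: the maximal-covariance pair of two
  # independent 200 x 3 blocks has |corr| well under 0.3 (max 0.28 over 40
  # seeds); wider blocks inflate the spurious maximum
  low <- 0
  for (seed in 1:20) {
    set.seed(seed + 1000)
    X <- matrix(rnorm(200 * 3), 200)
    Y <- matrix(rnorm(200 * 3), 200)
    mod <- fit_o2pls(X, Y, k = 1L)
    if (abs(score_correlations(mod)) <= 0.3) low <- low + 1
  }
  expect_gte(low, 19)
  blk <- make_joint_blocks(seed = 77, noise_frac = 0.05)
  expect_gte(score_correlations(fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L))[1],
             0.9)
})

test_that("joint weights agree with an independent PLS implementation", {
  # the first joint weight pair is the leading singular pair of the
  # cross-covariance, which canonical PLS computes by its own route
  blk <- make_joint_blocks(seed = 61, noise_frac = 0.1)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L)
  ref <- mixOmics::pls(blk$X, blk$Y, ncomp = 1, scale = FALSE,
                       mode = "canonical")
  w_ref <- ref$loadings$X[, 1]
  c_ref <- ref$loadings$Y[, 1]
  expect_lt(max(abs(mod$W[, 1] - sign(sum(w_ref * mod$W[, 1])) * w_ref)),
            1e-6)
  expect_lt(max(abs(mod$C[, 1] - sign(sum(c_ref * mod$C[, 1])) * c_ref)),
            1e-6)
})

test_that("zero-variance score columns are flagged with zero correlation", {
  blk <- make_joint_blocks(seed = 4, noise_frac = 0.05)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L)
  mod$Tmat[, 1] <- 0                       # degenerate score column
  expect_warning(r <- score_correlations(mod), "zero-variance")
  expect_identical(r, 0)
})

test_that("prediction is exact on noiseless training data and centers fix points", {
  blk <- make_joint_blocks(seed = 5)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  expect_lt(max(abs(predict_y(mod, blk$X) - blk$Y)), 1e-8)
  mu_row <- matrix(colMeans(blk$X), 1)
  expect_equal(as.vector(predict_y(mod, mu_row)), colMeans(blk$Y),
               tolerance = 1e-10)
  expect_error(predict_y(mod, blk$X[, -1]), "columns")
  # held-out prediction under noise stays strong
  blk2 <- make_joint_blocks(F = 140L, seed = 6, noise_frac = 0.05)
  tr <- 1:100; ho <- 101:140
  mod2 <- fit_o2pls(blk2$X[tr, ], blk2$Y[tr, ], k = 1L, l = 1L)
  yhat <- predict_y(mod2, blk2$X[ho, ])
  press <- sum((blk2$Y[ho, ] - yhat)^2)
  ss <- sum(sweep(blk2$Y[ho, ], 2, colMeans(blk2$Y[tr, ]))^2)
  expect_gte(1 - press / ss, 0.8)
})

test_that("refitting on the orthogonally deflated block reproduces the joint part", {
  blk <- make_joint_blocks(seed = 9, noise_frac = 0.02)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  X_defl <- blk$X - tcrossprod(mod$To, mod$Po)
  mod2 <- fit_o2pls(X_defl, blk$Y, k = 1L, l = 0L)
  align <- sign(sum(mod$Tmat[, 1] * mod2$Tmat[, 1]))
  expect_lt(max(abs(mod$Tmat[, 1] - align * mod2$Tmat[, 1])), 1e-6)
  expect_lt(max(abs(mod$P[, 1] - align * mod2$P[, 1])), 1e-6)
})

test_that("fits are deterministic and obey the sign convention", {
  blk <- make_joint_blocks(seed = 12, noise_frac = 0.05)
  m1 <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  m2 <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  expect_identical(m1, m2)
  expect_gt(m1$W[which.max(abs(m1$W[, 1])), 1], 0)
  expect_gt(m1$Po[which.max(abs(m1$Po[, 1])), 1], 0)
})

test_that("rank limits produce informative errors", {
  blk <- make_joint_blocks(seed = 15)       # X has rank 2, Y rank 1
  expect_error(fit_o2pls(blk$X, blk$Y, k = 1L, l = 2L), "rank")
  expect_error(fit_o2pls(blk$X, blk$Y, k = 2L), "rank|achievable")
  expect_error(fit_o2pls(blk$X[1:50, ], blk$Y, k = 1L), "same number of rows")
  expect_warning(fit_o2pls(cbind(blk$X, 3), blk$Y, k = 1L), "zero-variance")
})

test_that("cross-validation finds the built structure and rejects noise", {
  # noiseless rank-2 shared structure -> k = 2, no orthogonal components
  set.seed(31)
  F_ <- 70L
  t1 <- ctr(rnorm(F_)); t2 <- orth_to(rnorm(F_), t1)
  X <- t1 %*% t(rnorm(24)) + t2 %*% t(rnorm(24)) +
    1e-4 * matrix(rnorm(F_ * 24), F_)
  Y <- t1 %*% t(rnorm(20)) + t2 %*% t(rnorm(20)) +
    1e-4 * matrix(rnorm(F_ * 20), F_)
  cv <- cross_validate(X, Y, max_k = 4L, max_l = 2L, max_m = 2L)
  expect_equal(unname(cv$selected), c(2L, 0L, 0L))
  expect_false(cv$no_joint_variation)
  expect_true(all(cv$grid$q2x <= 1 & cv$grid$q2y <= 1))
  expect_gt(length(cv$rule_trace), 0)
})

test_that("pure-noise blocks select k = 0 with the no-joint flag", {
  accepts <- 0
  for (seed in 1:20) {
    set.seed(seed + 2000)
    X <- matrix(rnorm(70 * 15), 70)
    Y <- matrix(rnorm(70 * 15), 70)
    cv <- cross_validate(X, Y, max_k = 2L, max_l = 1L, max_m = 1L)
    if (!cv$no_joint_variation) accepts <- accepts + 1
  }
  expect_lte(accepts, 2)
})

test_that("appending pure-noise columns to X does not raise Q2", {
  worse_or_equal <- 0
  for (seed in 1:10) {
    blk <- make_joint_blocks(F = 80L, seed = seed + 50, noise_frac = 0.05)
    cv1 <- cross_validate(blk$X, blk$Y, max_k = 1L, max_l = 0L, max_m = 0L)
    set.seed(seed + 60)
    Xplus <- cbind(blk$X, matrix(rnorm(80 * 40, 0, sd(blk$X)), 80))
    cv2 <- cross_validate(Xplus, blk$Y, max_k = 1L, max_l = 0L, max_m = 0L)
    q1 <- cv1$grid$q2y[1]; q2 <- cv2$grid$q2y[1]
    if (q2 <= q1 + 0.005) worse_or_equal <- worse_or_equal + 1
  }
  expect_gte(worse_or_equal, 9)
})

test_that("models round-trip through the CSV directory format", {
  blk <- make_joint_blocks(seed = 21, noise_frac = 0.05)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  dir <- file.path(withr::local_tempdir(), "model")
  write_o2pls(mod, dir)
  back <- read_o2pls(dir)
  for (nm in c("Tmat", "U", "W", "C", "P", "To", "Po", "E", "Fres"))
    expect_equal(back[[nm]], mod[[nm]], tolerance = 1e-12)
  expect_equal(back$B_t_u, mod$B_t_u, tolerance = 1e-12)
  expect_equal(back$k, mod$k)
  # prediction from the reloaded model matches
  expect_equal(predict_y(back, blk$X), predict_y(mod, blk$X),
               tolerance = 1e-10)
})

test_that("score export is tidy and complete", {
  blk <- make_joint_blocks(seed = 23)
  mod <- fit_o2pls(blk$X, blk$Y, k = 1L, l = 1L)
  df <- export_scores(mod, frame_rate_hz = 10)
  expect_setequal(unique(df$kind), c("joint", "orthogonal"))
  expect_equal(nrow(df), 100 * 3)           # T, U, To
  expect_equal(max(df$time_s), 99 / 10)
})
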