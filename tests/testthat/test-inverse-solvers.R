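test_that("SNR-indexed regularization follows the dB definition and is monotone", {
  w <- small_world()
  nm <- noise_model(n_channels = nrow(w$lf$matrix))
  # 0 dB with trace(LL') = trace(C): lambda2 = 1 exactly
  L0 <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)  # trace(LL') = 3
  lf0 <- new_leadfield(L0)
  nm0 <- noise_model(diag(2) * 1.5)        # trace(C) = 3
  expect_equal(regularization_from_snr(lf0, nm0, 0), 1.0)
  # dB arithmetic: +10 dB divides lambda2 by 10
  expect_equal(regularization_from_snr(lf0, nm0, 10),
               regularization_from_snr(lf0, nm0, 0) / 10)
  # default working point 2.5 dB on the real leadfield: direct evaluation
  expect_equal(regularization_from_snr(w$lf, nm, 2.5),
               sum(w$lf$matrix^2) / (nrow(w$lf$matrix) * 10^0.25))
  # strictly decreasing over the -10..10 dB sweep
  sweep <- vapply(seq(-10, 10, by = 2.5), function(s)
    regularization_from_snr(w$lf, nm, s), numeric(1))
  expect_true(all(diff(sweep) < 0))
})

test_that("LSMN operator matches its closed form and limits", {
  # square orthonormal L, lambda2 = 0: Phi = L', Phi L = I
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  lfq <- new_leadfield(q)
  nm <- noise_model(n_channels = 4)
  op <- lsmn_operator(lfq, nm, rep(1, 4), 0)
  expect_equal(op$filters, t(q), tolerance = 1e-10)
  expect_equal(op$filters %*% q, diag(4), tolerance = 1e-10)

  # explicit closed form on a printed 2x3 toy
  L <- matrix(c(1, 0, 0.5, 1, 0, 1), 2, 3)
  wdiag <- c(1, 2, 0.5)
  lam <- 0.3
  lft <- new_leadfield(L)
  got <- lsmn_operator(lft, noise_model(n_channels = 2), wdiag, lam)$filters
  W <- diag(wdiag)
  want <- W %*% t(L) %*% solve(L %*% W %*% t(L) + lam * diag(2))
  expect_equal(got, want, tolerance = 1e-12)

  # infinite-regularization limit: operator vanishes
  huge <- lsmn_operator(lft, noise_model(n_channels = 2), wdiag, 1e12)
  expect_lt(max(abs(huge$filters)), 1e-10)

  # W = I, lambda2 = 0, full-row-rank L reproduces the pseudo-inverse
  set.seed(1)
  L2 <- matrix(rnorm(12), 3, 4)
  got2 <- lsmn_operator(new_leadfield(L2), noise_model(n_channels = 3),
                        rep(1, 4), 0)$filters
  sv <- svd(L2)
  want2 <- sv$v %*% ((1 / sv$d) * t(sv$u))  # independent SVD pseudo-inverse
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("prior weight constructors behave as documented", {
  w <- small_world()
  expect_identical(mne_weights(w$lf), rep(1, ncol(w$lf$matrix)))

  # column norms (1, 2), exponent 1: weights prop (1, 0.5), mean-1 rescale
  L <- cbind(c(1, 0), c(0, 2))
  wd <- wmne_weights(new_leadfield(L), exponent = 1)
  expect_equal(wd, c(4 / 3, 2 / 3))
  expect_equal(wmne_weights(new_leadfield(L), exponent = 0),
               mne_weights(new_leadfield(L)))
  expect_error(wmne_weights(new_leadfield(cbind(c(1, 0), c(0, 0)))),
               "dipole 2")

  # equal column norms: all ones after rescale
  Leq <- cbind(c(1, 0), c(0, 1))
  expect_equal(wmne_weights(new_leadfield(Leq)), c(1, 1))
})

test_that("eLORETA weights solve the fixed point and give exact localization", {
  w <- small_world()
  nm <- noise_model(n_channels = nrow(w$lf$matrix))
  lam <- regularization_from_snr(w$lf, nm, 2.5)
  ew <- eloreta_weights(w$lf, nm, lam)
  expect_true(ew$converged)
  expect_lt(ew$iterations, 100)
  # fixed-point residual (up to the mean-1 rescale) within tolerance
  L <- w$lf$matrix
  LW <- sweep(L, 2, ew$prior_diag, "*")
  M <- solve(LW %*% t(L) + lam * nm$covariance)
  w_star <- colSums(L * (M %*% L))^(-1 / 2)
  w_star <- w_star / mean(w_star)
  expect_equal(ew$prior_diag, w_star, tolerance = 1e-5)

  # square orthonormal L, lambda2 = 0: W converges to ones, Phi L = I
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  lfq <- new_leadfield(q)
  ewq <- eloreta_weights(lfq, noise_model(n_channels = 5), 0)
  expect_equal(ewq$prior_diag, rep(1, 5), tolerance = 1e-6)
  opq <- lsmn_operator(lfq, noise_model(n_channels = 5), ewq$prior_diag, 0)
  expect_equal(opq$filters %*% q, diag(5), tolerance = 1e-8)
})

test_that("sLORETA standardization matches hand algebra and yields positive diagonals", {
  # hand-evaluated 2x3 toy
  L <- matrix(c(1, 0, 0.5, 1, 0, 1), 2, 3)
  lam <- 0.2
  lft <- new_leadfield(L)
  nm <- noise_model(n_channels = 2)
  op <- sloreta_operator(lft, nm, lam)
  G <- L %*% t(L) + lam * diag(2)
  phi_mne <- t(L) %*% solve(G)
  sigma2 <- diag(phi_mne %*% G %*% t(phi_mne))
  expect_equal(op$filters, phi_mne / sqrt(sigma2), tolerance = 1e-12)
  expect_identical(op$units, "normalized")

  # standardized resolution diagonal strictly positive
  R <- op$filters %*% L
  expect_true(all(diag(R) > 0))
})

test_that("beamformers satisfy unit gain / unit norm and the identity-covariance closed form", {
  w <- small_world()
  dcov <- cov(t(w$rec$data))
  gamma <- 10^(-2.5 / 10)
  lcmv <- lcmv_operator(w$lf, dcov, gamma)
  gains <- rowSums(lcmv$filters * t(w$lf$matrix))
  expect_equal(gains, rep(1, ncol(w$lf$matrix)), tolerance = 1e-8)

  ungmv <- ungmv_operator(w$lf, dcov, gamma)
  expect_equal(sqrt(rowSums(ungmv$filters^2)),
               rep(1, nrow(ungmv$filters)), tolerance = 1e-10)
  # pure row rescaling: directions identical to LCMV
  scale <- sqrt(rowSums(lcmv$filters^2))
  expect_equal(ungmv$filters, lcmv$filters / scale, tolerance = 1e-12)

  # identity covariance (gamma = 0): Phi_j = l_j' / ||l_j||^2
  lf1 <- new_leadfield(cbind(c(3, 4)))
  op1 <- lcmv_operator(lf1, diag(2), 0)
  expect_equal(op1$filters, t(cbind(c(3, 4))) / 25, tolerance = 1e-12)

  # two-source closed form: filter output variance on a known 2x2 model
  A <- matrix(c(1, 0.3, 0.2, 1), 2, 2)
  P <- diag(c(2, 1))                      # source powers
  Cx <- A %*% P %*% t(A) + 0.1 * diag(2)  # sensor covariance
  op2 <- lcmv_operator(new_leadfield(A), Cx, 0)
  for (j in 1:2) {
    lj <- A[, j]
    want_var <- 1 / drop(t(lj) %*% solve(Cx) %*% lj)  # analytic output power
    got_var <- drop(op2$filters[j, , drop = FALSE] %*% Cx %*%
                    t(op2$filters[j, , drop = FALSE]))
    expect_equal(got_var, want_var, tolerance = 1e-12)
  }
})

test_that("apply_inverse is the exact linear map with metadata propagation", {
  w <- small_world()
  dcov <- cov(t(w$rec$data))
  op <- make_inverse_operator(w$lf, "mne", snr_db = 2.5)
  # zero in, zero out
  zero <- w$rec; zero$data[] <- 0
  expect_true(all(apply_inverse(op, zero)$data == 0))
  # identity filters reproduce the recording
  opI <- op; opI$filters <- diag(nrow(w$rec$data))
  expect_equal(apply_inverse(opI, w$rec)$data, w$rec$data)
  # superposition to machine precision
  a <- 2.5; b <- -1.25
  x <- w$rec; y <- w$rec
  set.seed(8); y$data <- matrix(rnorm(length(y$data)), nrow(y$data))
  comb <- w$rec; comb$data <- a * x$data + b * y$data
  expect_equal(apply_inverse(op, comb)$data,
               a * apply_inverse(op, x)$data + b * apply_inverse(op, y)$data,
               tolerance = 1e-12)
  expect_error(apply_inverse(op, w$rec$data[-1, ]), "mismatch")
  expect_identical(apply_inverse(op, w$rec)$algorithm, "mne")
})

test_that("make_inverse_operator covers all six algorithms with one SNR knob", {
  w <- small_world()
  dcov <- cov(t(w$rec$data))
  for (alg in algorithm_names()) {
    op <- make_inverse_operator(w$lf, alg, snr_db = 2.5, data_cov = dcov)
    expect_s3_class(op, "inverse_operator")
    expect_identical(op$algorithm, alg)
    expect_equal(dim(op$filters), c(ncol(w$lf$matrix), nrow(w$lf$matrix)))
    expect_true(all(is.finite(op$filters)))
  }
  expect_error(make_inverse_operator(w$lf, "lcmv"), "data_cov")
  expect_identical(
    make_inverse_operator(w$lf, "ungmv", data_cov = dcov)$units,
    "normalized")
})
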