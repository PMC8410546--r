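# The six linear inverse operators on a shared SNR-indexed regularization
# scale.  LSMN family: Phi = W L' (L W L' + lambda2 C)^-1 with a diagonal
# source-covariance prior W (MNE W = I, wMNE depth weights, eLORETA
# fixed-point weights, sLORETA = standardized MNE).  Beamformers (LCMV,
# UNGMV) are built per dipole from the data covariance.

#' Noise model for LSMN regularization
#'
#' @param covariance symmetric positive semi-definite channel covariance;
#'   defaults to the identity when only \code{n_channels} is given.
#' @param n_channels channel count (used when \code{covariance} is NULL).
#' @param source provenance label: \code{"identity"} or
#'   \code{"empty_room_sample"}.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(covariance = NULL, n_channels = NULL,
                        source = c("identity", "empty_room_sample")) {
  source <- match.arg(source)
  if (is.null(covariance)) {
    if (is.null(n_channels)) stop("need covariance or n_channels",
                                  call. = FALSE)
    covariance <- diag(n_channels)
  }
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) > 1e-10 * max(1, max(abs(covariance))))
    stop("noise covariance must be symmetric", call. = FALSE)
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * sum(diag(covariance)))
    stop("noise covariance must be positive semi-definite", call. = FALSE)
  structure(list(covariance = covariance, source = source),
            class = "noise_model")
}

#' Empty-room sample noise covariance
#'
#' @param rec an empty-room \code{recording}.
#' @return a \code{noise_model} built from the sample channel covariance.
#' @export
empty_room_noise_model <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  noise_model(stats::cov(t(rec$data)), source = "empty_room_sample")
}

#' Regularization parameter from predicted SNR
#'
#' Maps a predicted SNR in dB to the Tikhonov parameter via
#' \code{lambda2 = trace(L W L') / (trace(C) * 10^(snr_db/10))} (power-scale
#' SNR; W is the identity at call time, solver-specific priors rescale
#' internally). Strictly decreasing in \code{snr_db}, giving one SNR knob
#' shared by all six algorithms.
#'
#' @param leadfield a \code{leadfield}.
#' @param noise a \code{noise_model}.
#' @param snr_db predicted SNR in dB.
#' @return the scalar \code{lambda2}.
#' @export
regularization_from_snr <- function(leadfield, noise, snr_db) {
  stopifnot_scalar(snr_db, "snr_db")
  L <- leadfield$matrix
  num <- sum(L^2)  # trace(L L')
  if (num <= 0) stop("zero leadfield", call. = FALSE)
  den <- sum(diag(noise$covariance))
  if (den <= 0) stop("noise covariance has non-positive trace", call. = FALSE)
  num / (den * 10^(snr_db / 10))
}

new_inverse_operator <- function(filters, algorithm, lambda2 = NA_real_,
                                 snr_db = NA_real_, prior_diag = NULL,
                                 iterations = NA_integer_, converged = TRUE,
                                 units = "current_density") {
  structure(list(filters = filters, algorithm = algorithm,
                 lambda2 = lambda2, snr_db = snr_db,
                 prior_diag = prior_diag, iterations = iterations,
                 converged = converged, units = units),
            class = "inverse_operator")
}

#' Generic regularized least-squares minimum-norm operator
#'
#' \code{Phi = W L' (L W L' + lambda2 C)^-1} with diagonal prior source
#' covariance \code{W = diag(prior_diag)}. Falls back to the pseudo-inverse
#' when the bracketed Gram matrix is singular (e.g. \code{lambda2 = 0} with
#' a rank-deficient leadfield).
#'
#' @param leadfield a \code{leadfield}.
#' @param noise a \code{noise_model}.
#' @param prior_diag per-dipole positive prior variances.
#' @param lambda2 regularization parameter (>= 0).
#' @param algorithm label stored on the result.
#' @return an \code{inverse_operator}.
#' @export
lsmn_operator <- function(leadfield, noise, prior_diag, lambda2,
                          algorithm = "mne") {
  L <- leadfield$matrix
  if (length(prior_diag) != ncol(L) || any(prior_diag <= 0))
    stop("prior_diag must be positive, one entry per dipole", call. = FALSE)
  if (lambda2 < 0) stop("lambda2 must be >= 0", call. = FALSE)
  LW <- sweep(L, 2, prior_diag, "*")       # L W
  gram <- LW %*% t(L) + lambda2 * noise$covariance
  # Phi' = gram^-1 (L W) solved column-block-wise
  phi <- t(sym_solve(gram, LW))
  new_inverse_operator(phi, algorithm, lambda2 = lambda2,
                       prior_diag = prior_diag)
}

#' MNE prior weights (identity)
#'
#' @param leadfield a \code{leadfield}.
#' @return a vector of ones, one per dipole.
#' @export
mne_weights <- function(leadfield) rep(1, ncol(leadfield$matrix))

#' Depth-weighted MNE prior weights
#'
#' Prior variances inversely proportional to the leadfield column norms
#' (\code{exponent = 1}; 2 gives norm-squared weighting), rescaled to mean 1
#' so the lambda2 scale stays comparable across algorithms.
#'
#' @param leadfield a \code{leadfield}.
#' @param exponent depth-weighting exponent (default 1).
#' @return per-dipole prior variances, mean 1.
#' @export
wmne_weights <- function(leadfield, exponent = 1) {
  cn <- leadfield$column_norms
  zero <- which(cn == 0)
  if (length(zero) > 0)
    stop(sprintf("zero leadfield column at dipole %d", zero[1]),
         call. = FALSE)
  w <- cn^(-exponent)
  w / mean(w)
}

#' eLORETA prior weights by fixed-point iteration
#'
#' Iterates \code{M = (L W L' + lambda2 C)^-1};
#' \code{W_jj = (l_j' M l_j)^(-1/2)} (rescaled to mean 1 each pass) until
#' the maximum relative change in W drops below \code{tol} or
#' \code{max_iter} is hit. At the fixed point the operator attains exact
#' (zero peak-displacement) localization.
#'
#' @param leadfield a \code{leadfield}.
#' @param noise a \code{noise_model}.
#' @param lambda2 regularization parameter.
#' @param tol convergence tolerance on the max relative diagonal change.
#' @param max_iter iteration cap; non-convergence sets a flag, it is not an
#'   error.
#' @return list with \code{prior_diag}, \code{iterations}, \code{converged}.
#' @export
eloreta_weights <- function(leadfield, noise, lambda2, tol = 1e-6,
                            max_iter = 100) {
  L <- leadfield$matrix
  w <- rep(1, ncol(L))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    LW <- sweep(L, 2, w, "*")
    gram <- LW %*% t(L) + lambda2 * noise$covariance
    M <- tryCatch(solve(gram), error = function(e) pinv(gram))
    # l_j' M l_j for all j at once
    quad <- colSums(L * (M %*% L))
    if (any(quad <= 0)) stop("non-positive eLORETA quadratic form",
                             call. = FALSE)
    w_new <- quad^(-1 / 2)
    w_new <- w_new / mean(w_new)
    delta <- max(abs(w_new - w) / pmax(abs(w), .Machine$double.eps))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("eLORETA weights did not converge within max_iter")
  list(prior_diag = w, iterations = iter, converged = converged)
}

#' sLORETA operator (standardized MNE)
#'
#' Builds the MNE operator (W = I), then rescales each row by the square
#' root of its theoretical output variance
#' \code{sigma2_j = [Phi (L L' + lambda2 C) Phi']_jj}, yielding
#' unit-theoretical-variance (normalized) estimates with exact localization.
#'
#' @inheritParams lsmn_operator
#' @return an \code{inverse_operator} with \code{units = "normalized"}.
#' @export
sloreta_operator <- function(leadfield, noise, lambda2) {
  L <- leadfield$matrix
  mne <- lsmn_operator(leadfield, noise, mne_weights(leadfield), lambda2,
                       algorithm = "mne")
  phi <- mne$filters
  data_gram <- L %*% t(L) + lambda2 * noise$covariance
  sigma2 <- rowSums((phi %*% data_gram) * phi)
  if (any(sigma2 <= 0)) stop("non-positive sLORETA variance", call. = FALSE)
  out <- new_inverse_operator(phi / sqrt(sigma2), "sloreta",
                              lambda2 = lambda2, prior_diag = mne$prior_diag,
                              units = "normalized")
  out
}

#' LCMV beamformer operator
#'
#' Per-dipole minimum-variance filters with the unit-gain constraint
#' \code{Phi_j l_j = 1}: \code{Phi_j = (l_j' Creg^-1 l_j)^-1 l_j' Creg^-1}
#' with diagonal loading \code{Creg = C_data + gamma (trace(C_data)/Nx) I}.
#'
#' @param leadfield a \code{leadfield}.
#' @param data_cov channel covariance of the data being analyzed (sample
#'   covariance from at least ~800 samples is advisable).
#' @param gamma diagonal-loading factor; tie to predicted SNR via
#'   \code{gamma = 10^(-snr_db/10)}.
#' @return an \code{inverse_operator} with per-dipole unit gain.
#' @export
lcmv_operator <- function(leadfield, data_cov, gamma) {
  L <- leadfield$matrix
  nx <- nrow(L)
  data_cov <- as.matrix(data_cov)
  if (max(abs(data_cov - t(data_cov))) > 1e-8 * max(1, max(abs(data_cov))))
    stop("data covariance must be symmetric", call. = FALSE)
  creg <- data_cov + gamma * (sum(diag(data_cov)) / nx) * diag(nx)
  ci_l <- tryCatch(solve(creg, L), error = function(e) {
    if (gamma == 0)
      stop("singular data covariance; use gamma > 0 (diagonal loading)",
           call. = FALSE)
    pinv(creg) %*% L
  })
  quad <- colSums(L * ci_l)  # l_j' Creg^-1 l_j
  if (any(quad <= 0)) stop("non-positive beamformer quadratic form",
                           call. = FALSE)
  phi <- t(ci_l) / quad      # rows Phi_j = (quad_j)^-1 l_j' Creg^-1
  new_inverse_operator(phi, "lcmv", lambda2 = gamma)
}

#' Unit-noise-gain (UNGMV) beamformer operator
#'
#' LCMV filters rescaled row-wise to unit Euclidean norm; removes the
#' beamformer depth bias at the cost of current-density units.
#'
#' @inheritParams lcmv_operator
#' @return an \code{inverse_operator} with unit-norm rows and
#'   \code{units = "normalized"}.
#' @export
ungmv_operator <- function(leadfield, data_cov, gamma) {
  lcmv <- lcmv_operator(leadfield, data_cov, gamma)
  rn <- sqrt(rowSums(lcmv$filters^2))
  if (any(rn == 0)) stop("zero-norm beamformer filter row", call. = FALSE)
  new_inverse_operator(lcmv$filters / rn, "ungmv", lambda2 = lcmv$lambda2,
                       units = "normalized")
}

#' Build any of the six inverse operators by name
#'
#' One constructor covering the full algorithm set with the shared
#' SNR-indexed regularization: LSMN solvers get
#' \code{lambda2 = regularization_from_snr(...)}, beamformers get diagonal
#' loading \code{gamma = 10^(-snr_db/10)}.
#'
#' @param leadfield a \code{leadfield}.
#' @param algorithm one of \code{"lcmv"}, \code{"ungmv"}, \code{"mne"},
#'   \code{"wmne"}, \code{"sloreta"}, \code{"eloreta"}.
#' @param snr_db predicted SNR in dB (default 2.5).
#' @param noise a \code{noise_model}; identity by default.
#' @param data_cov channel data covariance (required for beamformers).
#' @param lambda2 optional explicit regularization overriding the SNR
#'   mapping (LSMN solvers only; \code{lambda2 = 0} gives the unregularized
#'   operator).
#' @param wmne_exponent depth-weighting exponent for wMNE.
#' @return an \code{inverse_operator} carrying the algorithm id,
#'   regularization, predicted SNR and (LSMN) prior diagonal.
#' @export
make_inverse_operator <- function(leadfield,
                                  algorithm = c("mne", "wmne", "sloreta",
                                                "eloreta", "lcmv", "ungmv"),
                                  snr_db = 2.5, noise = NULL,
                                  data_cov = NULL, lambda2 = NULL,
                                  wmne_exponent = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(noise)) noise <- noise_model(n_channels = nrow(leadfield$matrix))
  if (algorithm %in% c("lcmv", "ungmv")) {
    if (is.null(data_cov))
      stop("beamformers need `data_cov`", call. = FALSE)
    gamma <- if (is.null(lambda2)) 10^(-snr_db / 10) else lambda2
    op <- switch(algorithm,
                 lcmv = lcmv_operator(leadfield, data_cov, gamma),
                 ungmv = ungmv_operator(leadfield, data_cov, gamma))
    op$snr_db <- snr_db
    return(op)
  }
  if (is.null(lambda2))
    lambda2 <- regularization_from_snr(leadfield, noise, snr_db)
  op <- switch(algorithm,
    mne = lsmn_operator(leadfield, noise, mne_weights(leadfield), lambda2,
                        "mne"),
    wmne = lsmn_operator(leadfield, noise,
                         wmne_weights(leadfield, wmne_exponent), lambda2,
                         "wmne"),
    sloreta = sloreta_operator(leadfield, noise, lambda2),
    eloreta = {
      ew <- eloreta_weights(leadfield, noise, lambda2)
      out <- lsmn_operator(leadfield, noise, ew$prior_diag, lambda2,
                           "eloreta")
      out$iterations <- ew$iterations
      out$converged <- ew$converged
      out
    })
  op$snr_db <- snr_db
  op
}

#' All six algorithm names
#' @return character vector in the package's canonical order.
#' @export
algorithm_names <- function() {
  c("lcmv", "ungmv", "mne", "wmne", "sloreta", "eloreta")
}

#' Apply an inverse operator to a recording
#'
#' \code{s_hat = Phi x}; metadata (algorithm, units, sampling rate)
#' propagates to the estimate.
#'
#' @param op an \code{inverse_operator}.
#' @param rec a \code{recording} (or plain channels x samples matrix).
#' @return an object of class \code{source_estimate}: \code{data}
#'   (dipoles x samples), \code{algorithm}, \code{units}, \code{fs}.
#' @export
apply_inverse <- function(op, rec) {
  x <- if (inherits(rec, "recording")) rec$data else as.matrix(rec)
  if (ncol(op$filters) != nrow(x))
    stop("channel count mismatch between operator and recording",
         call. = FALSE)
  structure(list(data = op$filters %*% x, algorithm = op$algorithm,
                 units = op$units,
                 fs = if (inherits(rec, "recording")) rec$fs else NA_real_),
            class = "source_estimate")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("Inverse operator [%s]: %d dipoles x %d channels, lambda2 = %.4g, snr = %s dB\n",
              x$algorithm, nrow(x$filters), ncol(x$filters), x$lambda2,
              format(x$snr_db)))
  invisible(x)
}
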