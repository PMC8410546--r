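# Sensor-fold cross-validated variance explained.  Channels are partitioned
# into k folds; per fold the operator is rebuilt from the training rows of
# the leadfield, sources are reconstructed from training channels, forward
# mapped to the held-out channels, and the squared Pearson correlation per
# test sensor is averaged over all sensors and folds.  Running the identical
# pipeline on empty-room data gives the overfitting reference r2_ER, and the
# ratio r2_CV / r2_ER is the headline performance measure.

#' Algorithm specification for evaluation pipelines
#'
#' A lightweight recipe (algorithm + regularization settings) that pipeline
#' stages use to rebuild operators from arbitrary leadfield subsets.
#'
#' @param algorithm one of the six algorithm names.
#' @param snr_db predicted SNR in dB (default 2.5).
#' @param lambda2 optional explicit regularization (overrides the SNR
#'   mapping; 0 = unregularized).
#' @param wmne_exponent depth-weighting exponent for wMNE.
#' @return an object of class \code{algorithm_spec}.
#' @export
algorithm_spec <- function(algorithm, snr_db = 2.5, lambda2 = NULL,
                           wmne_exponent = 1) {
  algorithm <- match.arg(algorithm, algorithm_names())
  structure(list(algorithm = algorithm, snr_db = snr_db, lambda2 = lambda2,
                 wmne_exponent = wmne_exponent),
            class = "algorithm_spec")
}

# Build the operator described by `spec` from a leadfield and (for
# beamformers) the data whose covariance it should adapt to.
build_operator <- function(spec, leadfield, data = NULL) {
  data_cov <- NULL
  if (spec$algorithm %in% c("lcmv", "ungmv")) {
    if (is.null(data)) stop("beamformers need data for their covariance",
                            call. = FALSE)
    data_cov <- stats::cov(t(data))
  }
  make_inverse_operator(leadfield, spec$algorithm, snr_db = spec$snr_db,
                        data_cov = data_cov, lambda2 = spec$lambda2,
                        wmne_exponent = spec$wmne_exponent)
}

#' Random balanced sensor partition
#'
#' Splits channels into \code{k} random folds whose sizes differ by at most
#' one (e.g. 274 channels, 27 folds: 4 folds of 11 and 23 of 10). The same
#' partition must be reused across all algorithms on a given dataset so
#' per-fold training sets are identical.
#'
#' @param n_channels channel count.
#' @param k fold count (<= \code{n_channels}).
#' @param seed integer seed.
#' @return an object of class \code{sensor_partition}: \code{folds} (list of
#'   channel index vectors), \code{k}, \code{seed}.
#' @export
partition_sensors <- function(n_channels, k, seed = 1L) {
  if (k > n_channels) stop("k must be <= n_channels", call. = FALSE)
  sizes <- rep(n_channels %/% k, k)
  extra <- n_channels %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- with_seed(seed, sample.int(n_channels))
  folds <- split(perm, rep(seq_len(k), times = sizes))
  names(folds) <- NULL
  structure(list(folds = lapply(folds, sort), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "sensor_partition")
}

#' Default fold count for an arbitrary array
#'
#' Scales the 27-fold / 274-channel design to other arrays: about one fold
#' per 10.15 channels.
#'
#' @param n_channels channel count.
#' @return integer fold count (at least 2).
#' @export
default_fold_count <- function(n_channels) {
  max(2L, as.integer(round(n_channels / 10.15)))
}

# Rank-1 per-ROI parcellated reconstruction of a source matrix (dipoles x
# samples): project each ROI's time courses onto their first principal
# component and back-project via the loading vector (means restored).
parcellate_reconstruct <- function(s, atlas) {
  out <- s
  for (roi in seq_along(atlas$roi_cluster)) {
    idx <- which(atlas$dipole_roi == roi)
    if (length(idx) == 0) next
    block <- s[idx, , drop = FALSE]
    mu <- rowMeans(block)
    centered <- block - mu
    if (length(idx) == 1L) next  # rank-1 of one channel is the identity
    sv <- svd(centered, nu = 1, nv = 0)
    u1 <- pc_sign(sv$u[, 1])
    score <- drop(crossprod(u1, centered))      # 1 x T
    out[idx, ] <- mu + u1 %*% t(score)
  }
  out
}

# Deterministic PC sign convention: sum of loadings positive; tie broken to
# first nonzero entry positive.
pc_sign <- function(u) {
  s <- sum(u)
  if (s < 0) return(-u)
  if (s == 0) {
    nz <- u[u != 0]
    if (length(nz) > 0 && nz[1] < 0) return(-u)
  }
  u
}

#' Cross-validated variance explained
#'
#' For each fold: rebuild the inverse operator from the training rows of the
#' leadfield (beamformers use the training channels' sample covariance of
#' the same recording), reconstruct sources from the training channels,
#' forward-map to the held-out channels, and score each test sensor by the
#' squared Pearson correlation between its recorded and predicted time
#' series. The statistic is the average over all sensors. With
#' \code{partition = NULL} the fit is in-sample: the operator is built from
#' (and predictions are made at) all channels — the construction under which
#' the unregularized minimum-norm estimate explains 100\% of the variance of
#' any full-row-rank data.
#'
#' @param rec a \code{recording} (resting or empty-room; the pipeline is
#'   code-identical for both).
#' @param leadfield a \code{leadfield} for the same channels.
#' @param spec an \code{\link{algorithm_spec}}.
#' @param partition a \code{\link{partition_sensors}} result, or NULL for
#'   in-sample evaluation.
#' @param atlas optional \code{atlas}; if supplied, the reconstruction is
#'   replaced by its rank-1 per-ROI PCA parcellation before forward mapping.
#' @return list: \code{r2} (mean over sensors), \code{per_sensor}
#'   (data.frame channel/fold/r2), \code{n_excluded} (sensors with undefined
#'   correlation, excluded from the mean), \code{algorithm}.
#' @export
cross_validated_r2 <- function(rec, leadfield, spec, partition = NULL,
                               atlas = NULL) {
  x <- rec$data
  L <- leadfield$matrix
  if (nrow(x) != nrow(L))
    stop("recording/leadfield channel mismatch", call. = FALSE)
  folds <- if (is.null(partition)) list(NULL) else partition$folds
  rows <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- if (is.null(test)) seq_len(nrow(L)) else setdiff(seq_len(nrow(L)), test)
    if (is.null(test)) test <- seq_len(nrow(L))
    lf_train <- new_leadfield(L[train, , drop = FALSE])
    op <- build_operator(spec, lf_train, data = x[train, , drop = FALSE])
    s_hat <- op$filters %*% x[train, , drop = FALSE]
    if (!is.null(atlas)) s_hat <- parcellate_reconstruct(s_hat, atlas)
    x_hat <- L[test, , drop = FALSE] %*% s_hat
    r <- vapply(seq_along(test), function(i)
      safe_cor(x[test[i], ], x_hat[i, ]), numeric(1))
    rows[[f]] <- data.frame(channel = test, fold = f, r2 = r^2)
  }
  tab <- do.call(rbind, rows)
  structure(list(r2 = mean(tab$r2, na.rm = TRUE), per_sensor = tab,
                 n_excluded = sum(is.na(tab$r2)),
                 algorithm = spec$algorithm),
            class = "cv_r2")
}

#' Parcellated cross-validated variance explained
#'
#' \code{\link{cross_validated_r2}} with the reconstruction replaced, before
#' forward mapping, by its rank-1 per-ROI PCA approximation (first principal
#' component per ROI, back-projected via the loading vector). With one
#' dipole per ROI it equals the unparcellated statistic exactly.
#'
#' @inheritParams cross_validated_r2
#' @param atlas an \code{atlas} covering all dipoles.
#' @return as \code{\link{cross_validated_r2}}.
#' @export
parcellated_cross_validated_r2 <- function(rec, leadfield, spec, partition,
                                           atlas) {
  stopifnot(inherits(atlas, "atlas"))
  if (length(atlas$dipole_roi) != ncol(leadfield$matrix))
    stop("atlas does not cover the source space", call. = FALSE)
  cross_validated_r2(rec, leadfield, spec, partition, atlas = atlas)
}

#' Ratio of resting to empty-room variance explained
#'
#' \code{r2_cv / r2_er}: cross-validated variance explained normalized by
#' the extent to which the algorithm overfits non-brain signal.
#'
#' @param r2_cv variance explained on resting data (scalar or \code{cv_r2}).
#' @param r2_er variance explained on empty-room data (> 0).
#' @return the scalar ratio.
#' @export
ve_ratio <- function(r2_cv, r2_er) {
  if (inherits(r2_cv, "cv_r2")) r2_cv <- r2_cv$r2
  if (inherits(r2_er, "cv_r2")) r2_er <- r2_er$r2
  if (!is.finite(r2_er) || r2_er <= 0)
    stop("r2_er must be positive: ratio undefined", call. = FALSE)
  r2_cv / r2_er
}
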