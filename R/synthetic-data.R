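# Synthetic spherical-head MEG data: geometry, analytic forward model,
# distributed band-limited source dynamics, sensor/empty-room recordings and
# synthetic atlases.  Everything downstream is testable against these inputs.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic MEG study: array and source-space
#' sizes, epoch length and sampling rate, source frequency band, the local
#' spatial-correlation neighborhood, and the sensor SNR in dB. Defaults
#' emulate a desk-scale resting-state MEG session: a 30 s epoch at 256 Hz,
#' 1-100 Hz band-limited distributed sources, and 2.5 dB sensor SNR.
#'
#' @param n_sensors number of radial magnetometers (default 120).
#' @param n_dipoles number of source dipoles (default 600).
#' @param duration_s epoch length in seconds (default 30).
#' @param fs sampling rate in Hz (default 256).
#' @param band_hz length-2 source frequency band in Hz; clipped at Nyquist.
#' @param spatial_corr_neighbors neighbors per dipole in the k-nearest
#'   neighbor graph used for local spatial correlation (default 4; 0 disables
#'   smoothing and the graph has no edges).
#' @param snr_db sensor signal-to-noise ratio in dB (default 2.5).
#' @param seed integer seed; every generator is a pure function of
#'   (inputs, seed).
#' @return an object of class \code{sim_config}.
#' @export
simulation_config <- function(n_sensors = 120, n_dipoles = 600,
                              duration_s = 30, fs = 256,
                              band_hz = c(1, 100),
                              spatial_corr_neighbors = 4,
                              snr_db = 2.5, seed = 1L) {
  stopifnot_scalar(n_sensors, "n_sensors", positive = TRUE)
  stopifnot_scalar(n_dipoles, "n_dipoles", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[2] <= band_hz[1])
    stop("`band_hz` must be an increasing pair of non-negative frequencies",
         call. = FALSE)
  if (spatial_corr_neighbors < 0)
    stop("`spatial_corr_neighbors` must be >= 0", call. = FALSE)
  structure(list(n_sensors = as.integer(n_sensors),
                 n_dipoles = as.integer(n_dipoles),
                 duration_s = duration_s, fs = fs, band_hz = band_hz,
                 spatial_corr_neighbors = as.integer(spatial_corr_neighbors),
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "sim_config")
}

# Quasi-uniform points on a (hemi)sphere by the Fibonacci lattice.
fibonacci_sphere <- function(n, radius, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  # z in (-1, 1) for a full sphere, (0, 1) for the upper hemisphere
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  phi <- 2 * pi * i / golden
  rho <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

# Symmetric k-nearest-neighbor adjacency (logical, no self loops).
knn_graph <- function(pos, k) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  if (k > 0 && n > 1) {
    d <- distance_matrix(pos)
    diag(d) <- Inf
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[seq_len(min(k, n - 1L))]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)  # symmetrize
  }
  adj
}

#' Build a spherical head model
#'
#' Places radial magnetometers quasi-uniformly on the upper hemisphere of a
#' 0.12 m sphere and dipoles quasi-uniformly on a concentric 0.08 m sphere
#' (Fibonacci lattices), with seeded random tangential dipole orientations.
#' Tangential orientations are deliberate: radial dipoles are magnetically
#' silent in a spherical conductor and would produce all-zero leadfield
#' columns.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an object of class \code{head_model} with fields
#'   \code{sensor_positions}, \code{sensor_orientations},
#'   \code{dipole_positions}, \code{dipole_orientations},
#'   \code{neighbor_graph}, \code{sphere_center}.
#' @export
build_spherical_head <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sensors < 8L || config$n_dipoles < 8L)
    stop("need at least 8 sensors and 8 dipoles", call. = FALSE)
  r_sens <- 0.12; r_src <- 0.08
  center <- c(0, 0, 0)
  sens <- fibonacci_sphere(config$n_sensors, r_sens, hemisphere = TRUE)
  dip <- fibonacci_sphere(config$n_dipoles, r_src, hemisphere = FALSE)
  sens_orient <- sens / r_sens  # radial magnetometers
  # seeded random tangential unit orientations
  dip_orient <- with_seed(config$seed, {
    raw <- matrix(stats::rnorm(3 * config$n_dipoles), ncol = 3)
    radial <- dip / r_src
    tang <- raw - radial * rowSums(raw * radial)
    tang / sqrt(rowSums(tang^2))
  })
  graph <- knn_graph(dip, config$spatial_corr_neighbors)
  structure(list(sensor_positions = sens,
                 sensor_orientations = sens_orient,
                 dipole_positions = dip,
                 dipole_orientations = dip_orient,
                 neighbor_graph = graph,
                 sphere_center = center),
            class = "head_model")
}

# Sarvas closed-form magnetic field of a current dipole in a homogeneous
# spherical conductor.  Positions relative to the sphere center; Q in A*m,
# B in tesla.
sarvas_field <- function(r_sensor, r_dipole, q) {
  mu0_4pi <- 1e-7
  a_vec <- r_sensor - r_dipole
  a <- sqrt(sum(a_vec^2))
  r <- sqrt(sum(r_sensor^2))
  if (a < 1e-12) stop("dipole coincides with a sensor", call. = FALSE)
  adotr <- sum(a_vec * r_sensor)
  f <- a * (r * a + r^2 - sum(r_dipole * r_sensor))
  grad_f <- (a^2 / r + adotr / a + 2 * a + 2 * r) * r_sensor -
    (a + 2 * r + adotr / a) * r_dipole
  qxr0 <- c(q[2] * r_dipole[3] - q[3] * r_dipole[2],
            q[3] * r_dipole[1] - q[1] * r_dipole[3],
            q[1] * r_dipole[2] - q[2] * r_dipole[1])
  mu0_4pi / f^2 * (f * qxr0 - sum(qxr0 * r_sensor) * grad_f)
}

#' Compute the leadfield matrix
#'
#' Analytic forward model: entry (i, j) is the projection onto sensor i's
#' orientation of the magnetic field produced at sensor i by a unit
#' tangential current dipole at source j inside a homogeneous spherical
#' conductor (Sarvas closed form). Units: tesla per ampere-meter.
#'
#' @param head a \code{\link{build_spherical_head}} result.
#' @return an object of class \code{leadfield} with fields \code{matrix}
#'   (sensors x dipoles), \code{column_norms}, \code{channel_ids},
#'   \code{dipole_ids}.
#' @export
compute_leadfield <- function(head) {
  stopifnot(inherits(head, "head_model"))
  ns <- nrow(head$sensor_positions)
  nd <- nrow(head$dipole_positions)
  ctr <- head$sphere_center
  L <- matrix(0, ns, nd)
  for (j in seq_len(nd)) {
    r0 <- head$dipole_positions[j, ] - ctr
    q <- head$dipole_orientations[j, ]
    for (i in seq_len(ns)) {
      b <- sarvas_field(head$sensor_positions[i, ] - ctr, r0, q)
      L[i, j] <- sum(b * head$sensor_orientations[i, ])
    }
  }
  if (any(!is.finite(L))) stop("non-finite leadfield entries", call. = FALSE)
  new_leadfield(L)
}

#' Construct a leadfield object from a matrix
#'
#' @param L sensors x dipoles real matrix.
#' @param channel_ids,dipole_ids optional id vectors.
#' @return a \code{leadfield} object; column norms are computed and cached.
#' @export
new_leadfield <- function(L, channel_ids = NULL, dipole_ids = NULL) {
  L <- as.matrix(L)
  if (any(!is.finite(L))) stop("leadfield must be finite", call. = FALSE)
  cn <- sqrt(colSums(L^2))
  structure(list(matrix = L, column_norms = cn,
                 channel_ids = channel_ids %||% seq_len(nrow(L)),
                 dipole_ids = dipole_ids %||% seq_len(ncol(L))),
            class = "leadfield")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brick-wall band-pass filter of each row of x via the FFT: Fourier
# coefficients with |f| outside [lo, hi] are zeroed.  An ideal band-pass of
# Gaussian noise stays Gaussian and has exactly zero out-of-band power.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- ncol(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folded
  keep <- freqs >= lo & freqs <= hi
  xf <- t(apply(x, 1, stats::fft))
  xf[, !keep] <- 0
  t(apply(xf, 1, function(row) Re(stats::fft(row, inverse = TRUE)) / n))
}

#' Simulate distributed resting-state source dynamics
#'
#' Each dipole's time course is band-limited Gaussian noise (ideal band-pass
#' in the configured band, clipped at Nyquist), then one spatial-smoothing
#' pass averages each dipole with its graph neighbors to induce the local
#' spatial correlation that drives leakage-sensitive metrics. Time courses
#' are zero-mean per dipole.
#'
#' @param head a \code{head_model}.
#' @param config a \code{sim_config}.
#' @return an object of class \code{source_activity}: \code{data}
#'   (dipoles x samples, ampere-meter), \code{fs}.
#' @export
simulate_sources <- function(head, config) {
  stopifnot(inherits(head, "head_model"), inherits(config, "sim_config"))
  n <- nrow(head$dipole_positions)
  t_len <- round(config$duration_s * config$fs)
  if (t_len < 2) stop("epoch too short", call. = FALSE)
  lo <- config$band_hz[1]
  hi <- min(config$band_hz[2], config$fs / 2)
  s <- with_seed(config$seed, {
    raw <- matrix(stats::rnorm(n * t_len), nrow = n)
    filt <- fft_bandpass(raw, config$fs, lo, hi)
    if (config$spatial_corr_neighbors > 0 && any(head$neighbor_graph)) {
      # one smoothing pass: average each dipole with its neighbors
      w <- head$neighbor_graph * 1
      diag(w) <- 1
      filt <- (w / rowSums(w)) %*% filt
    }
    filt - rowMeans(filt)
  })
  # nominal source scale: 10 nA*m dipole moments
  structure(list(data = s * 1e-8, fs = config$fs),
            class = "source_activity")
}

#' Simulate a sensor recording at a controlled SNR
#'
#' Forms \code{L s} and adds i.i.d. Gaussian sensor noise scaled so that
#' \code{10*log10(mean channel variance of L s / noise population variance)}
#' equals \code{snr_db} exactly for this realization (population noise
#' scaling against the realized signal variance). \code{snr_db = Inf}
#' disables noise.
#'
#' @param leadfield a \code{leadfield}.
#' @param sources a \code{source_activity}.
#' @param snr_db SNR in dB (power scale); \code{Inf} for noiseless.
#' @param seed integer seed for the noise draw.
#' @return an object of class \code{recording}: \code{data}
#'   (channels x samples, tesla), \code{fs}, \code{kind = "resting"},
#'   \code{seed}.
#' @export
simulate_recording <- function(leadfield, sources, snr_db = 2.5, seed = 1L) {
  stopifnot(inherits(leadfield, "leadfield"),
            inherits(sources, "source_activity"))
  if (ncol(leadfield$matrix) != nrow(sources$data))
    stop("leadfield/source dimension mismatch", call. = FALSE)
  x <- leadfield$matrix %*% sources$data
  sig_var <- mean(apply(x, 1, stats::var))
  if (sig_var <= 0) stop("zero-variance signal: SNR undefined", call. = FALSE)
  if (is.finite(snr_db)) {
    noise_var <- sig_var / 10^(snr_db / 10)
    eta <- with_seed(seed, matrix(stats::rnorm(length(x), sd = sqrt(noise_var)),
                                  nrow = nrow(x)))
    x <- x + eta
  }
  structure(list(data = x, fs = sources$fs, kind = "resting",
                 seed = as.integer(seed)),
            class = "recording")
}

#' Simulate an empty-room recording
#'
#' Sensor-only noise: i.i.d. Gaussian per channel plus (by default) a rank-3
#' low-rank common-mode component emulating environmental noise shared
#' across sensors, so empty-room data is not perfectly white.
#'
#' @param n_sensors channel count.
#' @param duration_s epoch length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param common_mode_rank rank of the shared component (0 disables it).
#' @param common_mode_gain standard-deviation multiple of the sensor noise
#'   given to each common-mode component (default 5).
#' @param noise_sd per-channel sensor noise standard deviation in tesla.
#' @return a \code{recording} with \code{kind = "empty_room"}.
#' @export
simulate_empty_room <- function(n_sensors, duration_s, fs, seed = 1L,
                                common_mode_rank = 3, common_mode_gain = 5,
                                noise_sd = 1e-13) {
  stopifnot_scalar(n_sensors, "n_sensors", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  t_len <- round(duration_s * fs)
  x <- with_seed(seed, {
    out <- matrix(stats::rnorm(n_sensors * t_len, sd = noise_sd),
                  nrow = n_sensors)
    if (common_mode_rank > 0) {
      patterns <- matrix(stats::rnorm(n_sensors * common_mode_rank),
                         nrow = n_sensors)
      patterns <- sweep(patterns, 2, sqrt(colSums(patterns^2)), "/")
      courses <- matrix(stats::rnorm(common_mode_rank * t_len,
                                     sd = common_mode_gain * noise_sd),
                        nrow = common_mode_rank)
      out <- out + patterns %*% courses
    }
    out
  })
  structure(list(data = x, fs = fs, kind = "empty_room",
                 seed = as.integer(seed)),
            class = "recording")
}

#' Build a synthetic atlas over the dipole source space
#'
#' Partitions dipoles into spatially contiguous ROIs by k-means on dipole
#' positions (nearest-centroid assignment), then groups ROIs into clusters
#' by k-means on ROI centroids. ROI adjacency is derived from the dipole
#' neighbor graph: two ROIs are adjacent iff some dipole in one is a graph
#' neighbor of a dipole in the other.
#'
#' @param head a \code{head_model}.
#' @param n_rois number of ROIs (<= dipole count).
#' @param n_clusters number of ROI clusters (<= \code{n_rois}).
#' @param seed integer seed; reseeded internally (up to 10 attempts) if a
#'   k-means run leaves an empty ROI.
#' @return an object of class \code{atlas}: \code{dipole_roi} (per-dipole ROI
#'   id), \code{roi_cluster} (per-ROI cluster id), \code{roi_adjacency}
#'   (logical ROI x ROI), \code{names}.
#' @export
build_synthetic_atlas <- function(head, n_rois, n_clusters, seed = 1L) {
  stopifnot(inherits(head, "head_model"))
  nd <- nrow(head$dipole_positions)
  if (!(n_clusters <= n_rois && n_rois <= nd))
    stop("need n_clusters <= n_rois <= n_dipoles", call. = FALSE)
  pos <- head$dipole_positions
  for (attempt in seq_len(10)) {
    res <- with_seed(seed + attempt - 1L, {
      if (n_rois == nd) {
        list(cluster = seq_len(nd), centers = pos)
      } else {
        km <- stats::kmeans(pos, centers = n_rois, nstart = 5,
                            iter.max = 100)
        list(cluster = km$cluster, centers = km$centers)
      }
    })
    if (length(unique(res$cluster)) == n_rois) break
    if (attempt == 10) stop("empty ROI after 10 k-means attempts",
                            call. = FALSE)
  }
  roi_of <- res$cluster
  centers <- res$centers
  roi_cluster <- with_seed(seed, {
    if (n_clusters == n_rois) seq_len(n_rois)
    else stats::kmeans(centers, centers = n_clusters, nstart = 5,
                       iter.max = 100)$cluster
  })
  structure(list(dipole_roi = as.integer(roi_of),
                 roi_cluster = as.integer(roi_cluster),
                 roi_adjacency = roi_adjacency_from_graph(roi_of,
                                                          head$neighbor_graph),
                 names = paste0("ROI_", seq_len(n_rois))),
            class = "atlas")
}

# ROI adjacency from the dipole neighbor graph.
roi_adjacency_from_graph <- function(dipole_roi, graph) {
  n_rois <- max(dipole_roi)
  adj <- matrix(FALSE, n_rois, n_rois)
  edges <- which(graph, arr.ind = TRUE)
  if (nrow(edges) > 0) {
    a <- dipole_roi[edges[, 1]]
    b <- dipole_roi[edges[, 2]]
    keep <- a != b
    adj[cbind(a[keep], b[keep])] <- TRUE
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  adj
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("Spherical head model: %d sensors (r = %.3g m), %d dipoles (r = %.3g m)\n",
              nrow(x$sensor_positions),
              sqrt(sum(x$sensor_positions[1, ]^2)),
              nrow(x$dipole_positions),
              sqrt(sum(x$dipole_positions[1, ]^2))))
  invisible(x)
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Leadfield: %d channels x %d dipoles, column norms [%.3g, %.3g] T/(A m)\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$column_norms), max(x$column_norms)))
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording (%s): %d channels x %d samples at %g Hz\n",
              x$kind, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("Atlas: %d dipoles, %d ROIs, %d clusters\n",
              length(x$dipole_roi), length(x$roi_cluster),
              length(unique(x$roi_cluster))))
  invisible(x)
}
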