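# Sensor-noise robustness curves and between-algorithm similarity with
# normalized-cuts spectral clustering.

#' Add scaled white sensor noise to a recording
#'
#' Injects i.i.d. Gaussian noise of per-channel variance
#' \code{sigma2 * trace(Cx) / Nx}, with \code{Cx} the sample channel
#' covariance of the recording (so \code{sigma2} is noise variance as a
#' fraction of the mean channel variance).
#'
#' @param rec a \code{recording}.
#' @param sigma2 noise level (>= 0); 0 returns the recording unchanged.
#' @param seed integer seed.
#' @return a \code{recording} of the same kind.
#' @export
add_sensor_noise <- function(rec, sigma2, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (sigma2 == 0) return(rec)
  v <- sigma2 * mean(apply(rec$data, 1, stats::var))
  eta <- with_seed(seed, matrix(stats::rnorm(length(rec$data),
                                             sd = sqrt(v)),
                                nrow = nrow(rec$data)))
  out <- rec
  out$data <- rec$data + eta
  out
}

# Effective predicted SNR after injecting noise at level sigma2: the signal
# variance is held fixed while the injected variance sigma2 * (S + N0) is
# added to the noise budget, so on the power scale
# rho_new = rho0 / (1 + sigma2 * (1 + rho0)).
effective_snr_db <- function(snr_db, sigma2) {
  rho0 <- 10^(snr_db / 10)
  10 * log10(rho0 / (1 + sigma2 * (1 + rho0)))
}

#' Sensor-noise robustness curve
#'
#' For each noise level: inject scaled white noise, recompute the effective
#' predicted SNR (signal variance fixed, injected variance added to the
#' noise budget), rebuild the operator at that SNR, source reconstruct, and
#' correlate each dipole's time course with the noiseless solution
#' (averaged over dipoles). The curve's standard deviation across levels is
#' the single-number sensitivity of the algorithm to external noise.
#'
#' @param rec a \code{recording}.
#' @param leadfield the matching \code{leadfield}.
#' @param spec an \code{\link{algorithm_spec}}.
#' @param sigma2_grid increasing noise levels starting at 0.
#' @param seed integer seed for the noise draws.
#' @return an object of class \code{robustness_curve}: \code{sigma2_grid},
#'   \code{correlations} (mean over dipoles per level),
#'   \code{std_across_levels}, \code{algorithm}.
#' @export
noise_robustness <- function(rec, leadfield, spec, sigma2_grid =
                               c(0, 0.1, 0.25, 0.5, 1, 2, 4), seed = 1L) {
  if (length(sigma2_grid) == 0) stop("empty sigma2 grid", call. = FALSE)
  if (sigma2_grid[1] != 0) stop("sigma2 grid must start at 0", call. = FALSE)
  base_op <- build_operator(spec, leadfield, data = rec$data)
  s0 <- base_op$filters %*% rec$data
  cors <- vapply(seq_along(sigma2_grid), function(k) {
    sg <- sigma2_grid[k]
    if (sg == 0) return(1)
    noisy <- add_sensor_noise(rec, sg, seed = seed + k)
    spec_k <- spec
    if (is.null(spec$lambda2))
      spec_k$snr_db <- effective_snr_db(spec$snr_db, sg)
    op <- build_operator(spec_k, leadfield, data = noisy$data)
    s <- op$filters %*% noisy$data
    r <- vapply(seq_len(nrow(s)), function(i) safe_cor(s[i, ], s0[i, ]),
                numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  structure(list(sigma2_grid = sigma2_grid, correlations = cors,
                 std_across_levels = stats::sd(cors),
                 algorithm = spec$algorithm),
            class = "robustness_curve")
}

#' Similarity between two source estimates
#'
#' Mean over dipoles of the per-dipole temporal Pearson correlation between
#' two reconstructions of the same recording (signed; dipoles with a
#' constant time course in either estimate are excluded and counted).
#'
#' @param est_a,est_b \code{source_estimate}s (or matrices) of equal size.
#' @return the scalar mean correlation (attribute \code{n_excluded} carries
#'   the excluded-dipole count).
#' @export
algorithm_similarity <- function(est_a, est_b) {
  a <- if (inherits(est_a, "source_estimate")) est_a$data else as.matrix(est_a)
  b <- if (inherits(est_b, "source_estimate")) est_b$data else as.matrix(est_b)
  if (!all(dim(a) == dim(b))) stop("estimate dimension mismatch",
                                   call. = FALSE)
  r <- vapply(seq_len(nrow(a)), function(i) safe_cor(a[i, ], b[i, ]),
              numeric(1))
  structure(mean(r, na.rm = TRUE), n_excluded = sum(is.na(r)))
}

#' Pairwise similarity matrix over a set of source estimates
#'
#' @param estimates named list of \code{source_estimate}s for the same
#'   recording.
#' @return an object of class \code{similarity_matrix}: symmetric
#'   \code{matrix} with unit diagonal, \code{labels}.
#' @export
similarity_matrix <- function(estimates) {
  n <- length(estimates)
  if (n < 2) stop("need at least two estimates", call. = FALSE)
  labels <- names(estimates) %||% paste0("alg_", seq_len(n))
  m <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      v <- as.numeric(algorithm_similarity(estimates[[i]], estimates[[j]]))
      m[i, j] <- v
      m[j, i] <- v  # computed once, assigned symmetrically
    }
  }
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, labels = labels),
            class = "similarity_matrix")
}

# Exact normalized-cut cost of a bipartition (A, B) of a weight matrix.
ncut_cost <- function(w, in_a) {
  cut <- sum(w[in_a, !in_a, drop = FALSE])
  assoc_a <- sum(w[in_a, , drop = FALSE])
  assoc_b <- sum(w[!in_a, , drop = FALSE])
  if (assoc_a == 0 || assoc_b == 0) return(0)
  cut / assoc_a + cut / assoc_b
}

# Best bipartition of a weight matrix by the spectral Ncut relaxation: the
# second-smallest generalized eigenvector of (D - W, D) is swept over all
# thresholds in its value ordering and the split with the minimum exact
# Ncut is taken (deterministic; includes the sign split).
spectral_bipartition <- function(w) {
  n <- nrow(w)
  deg <- rowSums(w)
  # disconnected components (including zero-degree nodes) split at cost 0
  comp <- graph_components(w > 0)
  if (max(comp) > 1) {
    in_a <- comp == 1
    return(list(in_a = in_a, cost = 0))
  }
  # small problems (the six-algorithm case and any toy) admit the exact
  # minimum-Ncut bipartition by enumeration; the spectral sweep below is the
  # scalable relaxation used beyond that
  if (n <= 12) return(exact_bipartition(w))
  dis <- 1 / sqrt(deg)
  lap <- diag(n) - (dis * w) %*% diag(dis)  # normalized Laplacian
  lap <- (lap + t(lap)) / 2
  ev <- eigen(lap, symmetric = TRUE)
  z <- ev$vectors[, n - 1]                  # second-smallest eigenvalue
  y <- dis * z                              # generalized eigenvector
  ord <- order(y, seq_len(n))
  best <- NULL
  for (k in seq_len(n - 1)) {
    in_a <- rep(FALSE, n)
    in_a[ord[seq_len(k)]] <- TRUE
    cost <- ncut_cost(w, in_a)
    cand <- list(in_a = in_a, cost = cost)
    if (is.null(best) || cost < best$cost - 1e-12) best <- cand
    else if (abs(cost - best$cost) <= 1e-12) {
      # tie: lexicographically smallest index set containing node 1
      a1 <- sort(which(if (cand$in_a[1]) cand$in_a else !cand$in_a))
      b1 <- sort(which(if (best$in_a[1]) best$in_a else !best$in_a))
      if (paste(a1, collapse = ",") < paste(b1, collapse = ",")) best <- cand
    }
  }
  best
}

# Exact minimum-Ncut bipartition by enumeration (node 1 fixed to side A;
# ties resolved toward the lexicographically smallest side-A index set).
exact_bipartition <- function(w) {
  n <- nrow(w)
  best <- NULL
  for (code in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0)
    cost <- ncut_cost(w, in_a)
    if (is.null(best) || cost < best$cost - 1e-12)
      best <- list(in_a = in_a, cost = cost)
  }
  best
}

# Connected components of a logical adjacency matrix.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Normalized-cuts dendrogram of a similarity matrix
#'
#' Recursive two-way normalized-cuts partitioning. Small nodes (up to 12
#' items, which covers the six-algorithm case) are split by exact
#' minimum-Ncut enumeration; larger nodes use the spectral relaxation
#' (second-smallest generalized eigenvector of \code{(D - S, D)} with a
#' threshold sweep minimizing the exact Ncut). Negative similarities are
#' floored at zero for
#' clustering; each recorded split carries its exact Ncut cost (higher cost
#' = more strongly connected cluster being severed). Disconnected
#' similarity graphs split along components at cost 0 first.
#'
#' @param sim a \code{similarity_matrix} (or symmetric matrix with labels).
#' @return an object of class \code{cut_dendrogram}: a nested list of
#'   splits, each with \code{members}, \code{cost}, \code{left},
#'   \code{right} (leaves have \code{members} of length 1).
#' @export
normalized_cuts_dendrogram <- function(sim) {
  m <- if (inherits(sim, "similarity_matrix")) sim$matrix else as.matrix(sim)
  if (nrow(m) < 2) stop("need at least two items to cluster", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
    stop("similarity matrix must be symmetric", call. = FALSE)
  labels <- rownames(m) %||% paste0("alg_", seq_len(nrow(m)))
  w <- pmax(m, 0)
  diag(w) <- 0
  recurse <- function(idx) {
    if (length(idx) == 1)
      return(list(members = labels[idx], cost = NA_real_))
    sub <- w[idx, idx, drop = FALSE]
    bp <- spectral_bipartition(sub)
    left <- idx[bp$in_a]
    right <- idx[!bp$in_a]
    list(members = labels[idx], cost = bp$cost,
         left = recurse(left), right = recurse(right))
  }
  structure(recurse(seq_len(nrow(m))), class = "cut_dendrogram")
}

# Flatten a dendrogram's internal splits into a data.frame (for reports).
#' @export
as.data.frame.cut_dendrogram <- function(x, ...) {
  rows <- list()
  walk <- function(node) {
    if (is.null(node$left)) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      members = paste(node$members, collapse = "+"),
      left = paste(node$left$members, collapse = "+"),
      right = paste(node$right$members, collapse = "+"),
      cost = node$cost)
    walk(node$left); walk(node$right)
  }
  walk(x)
  do.call(rbind, rows)
}
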