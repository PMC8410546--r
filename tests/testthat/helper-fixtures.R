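# Shared small-scale fixtures, built once per test run.

small_config <- function(n_sensors = 32, n_dipoles = 60, duration_s = 4,
                         seed = 11L, ...) {
  simulation_config(n_sensors = n_sensors, n_dipoles = n_dipoles,
                    duration_s = duration_s, seed = seed, ...)
}

.fixture_env <- new.env()

small_world <- function() {
  if (is.null(.fixture_env$world)) {
    cfg <- small_config()
    head <- build_spherical_head(cfg)
    lf <- compute_leadfield(head)
    src <- simulate_sources(head, cfg)
    rec <- simulate_recording(lf, src, snr_db = 2.5, seed = 21L)
    .fixture_env$world <- list(cfg = cfg, head = head, lf = lf,
                               src = src, rec = rec)
  }
  .fixture_env$world
}

# Independent brute-force resolution-metric oracles (naive double loops).
oracle_pad <- function(R, pos) {
  n <- ncol(R)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best_j <- 1; best_v <- -Inf
    for (j in seq_len(n)) {
      v <- abs(R[j, i])
      if (v > best_v) { best_v <- v; best_j <- j }
    }
    out[i] <- if (best_v == 0) NA_real_ else
      sqrt(sum((pos[i, ] - pos[best_j, ])^2))
  }
  out
}

oracle_seps <- function(R, pos) {
  n <- ncol(R)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      d2 <- sum((pos[j, ] - pos[i, ])^2)
      num <- num + R[j, i]^2 * d2
      den <- den + R[j, i]^2
    }
    out[i] <- if (den == 0) NA_real_ else sqrt(num / den)
  }
  out
}

oracle_sect <- function(R, pos) {
  n <- nrow(R)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      d2 <- sum((pos[j, ] - pos[i, ])^2)
      num <- num + R[i, j]^2 * d2
      den <- den + R[i, j]^2
    }
    out[i] <- if (den == 0) NA_real_ else sqrt(num / den)
  }
  out
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# Exact minimum-Ncut bipartition by enumerating all proper bipartitions.
oracle_min_ncut <- function(w) {
  n <- nrow(w)
  best <- NULL
  for (code in 0:(2^(n - 1) - 2)) {
    in_a <- c(TRUE, bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0)
    cut <- sum(w[in_a, !in_a, drop = FALSE])
    aa <- sum(w[in_a, , drop = FALSE]); ab <- sum(w[!in_a, , drop = FALSE])
    cost <- if (aa == 0 || ab == 0) 0 else cut / aa + cut / ab
    if (is.null(best) || cost < best$cost) best <- list(in_a = in_a,
                                                        cost = cost)
  }
  best
}
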