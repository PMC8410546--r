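# Repeated-measures statistical battery: Friedman test across algorithms,
# pairwise exact Wilcoxon signed-rank tests, Benjamini-Hochberg FDR
# correction within each metric family.

#' Friedman rank test on a subjects x algorithms metric table
#'
#' Within-row ranks (average ranks for ties), chi-squared statistic
#' \code{12/(n k (k+1)) * sum R_j^2 - 3 n (k+1)} with an upper-tail
#' chi-squared p on k - 1 degrees of freedom. No tie correction is applied
#' (fully tied rows simply contribute nothing); without ties the statistic
#' is identical to \code{stats::friedman.test}. Perfectly consistent
#' rankings give \code{chi2 = n (k - 1)} exactly.
#'
#' @param table numeric matrix or data.frame: rows = subjects/simulations,
#'   columns = algorithms, no missing cells.
#' @return list: \code{chi2}, \code{df}, \code{p}.
#' @export
friedman_rank_test <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m))) stop("metric table must be complete",
                               call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 subjects and 2 algorithms", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  col_sums <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(col_sums^2) - 3 * n * (k + 1)
  chi2 <- max(chi2, 0)  # guard tiny negative round-off on fully tied tables
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's rule), absolute differences are
#' ranked with average ranks, and V = sum of ranks of positive differences.
#' For n <= \code{exact_max} remaining pairs the two-sided p is exact —
#' equivalent to enumerating all 2^n sign assignments (computed by dynamic
#' programming over the realized, possibly tied, ranks) — otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list: \code{statistic} (V), \code{p}, \code{n} (pairs used),
#'   \code{exact}.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null distribution of V over all 2^n sign assignments, by
    # convolution over the doubled (hence integer) realized ranks
    r2 <- as.integer(round(2 * r))
    dist <- 1
    for (ri in r2) {
      ext <- c(dist, numeric(ri))
      ext[(ri + 1):(ri + length(dist))] <-
        ext[(ri + 1):(ri + length(dist))] + dist
      dist <- ext / 2
    }
    support <- (seq_along(dist) - 1) / 2  # V values
    mu <- n * (n + 1) / 4
    p <- sum(dist[abs(support - mu) >= abs(v - mu) - 1e-9])
    return(list(statistic = v, p = min(1, p), n = as.integer(n),
                exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = v, p = p, n = as.integer(n), exact = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment \code{p_(i) m / i} with cumulative-minimum enforcement
#' from the largest p downward, clipped at 1, original order restored
#' (delegated to \code{stats::p.adjust(method = "BH")} after validation).
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Full statistical report over metric tables
#'
#' For each metric: one Friedman test plus all pairwise Wilcoxon signed-rank
#' tests between algorithm columns, with Benjamini-Hochberg correction
#' applied within that metric's family of pairwise tests.
#'
#' @param metric_tables named list of subjects x algorithms matrices (all
#'   with identical column names in identical order).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return an object of class \code{stats_report}: \code{friedman}
#'   (data.frame metric/chi2/df/p) and \code{pairwise} (data.frame metric,
#'   algo_a, algo_b, statistic, p_raw, p_adj, significant), plus
#'   \code{long} (box-plot-ready long-format values).
#' @export
build_stats_report <- function(metric_tables, alpha = 0.05) {
  if (length(metric_tables) == 0)
    return(structure(list(friedman = data.frame(), pairwise = data.frame(),
                          long = data.frame()),
                     class = "stats_report"))
  cols <- colnames(as.matrix(metric_tables[[1]]))
  fr_rows <- list(); pw_rows <- list(); long_rows <- list()
  for (metric in names(metric_tables)) {
    m <- as.matrix(metric_tables[[metric]])
    if (!identical(colnames(m), cols))
      stop("metric tables have misaligned algorithm columns", call. = FALSE)
    ft <- friedman_rank_test(m)
    fr_rows[[metric]] <- data.frame(metric = metric, chi2 = ft$chi2,
                                    df = ft$df, p = ft$p)
    pairs <- utils::combn(ncol(m), 2)
    pw <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      wt <- wilcoxon_signed_rank(m[, i], m[, j])
      data.frame(metric = metric, algo_a = cols[i], algo_b = cols[j],
                 statistic = wt$statistic, p_raw = wt$p)
    })
    pw <- do.call(rbind, pw)
    pw$p_adj <- bh_fdr(pw$p_raw)
    pw$significant <- pw$p_adj < alpha
    pw_rows[[metric]] <- pw
    long_rows[[metric]] <- data.frame(
      metric = metric,
      subject = rep(seq_len(nrow(m)), times = ncol(m)),
      algorithm = rep(cols, each = nrow(m)),
      value = as.vector(m))
  }
  structure(list(friedman = do.call(rbind, c(fr_rows,
                                             make.row.names = FALSE)),
                 pairwise = do.call(rbind, c(pw_rows,
                                             make.row.names = FALSE)),
                 long = do.call(rbind, c(long_rows,
                                         make.row.names = FALSE))),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Group statistics report\n")
  if (nrow(x$friedman) > 0) {
    cat("Friedman tests:\n")
    print(x$friedman, row.names = FALSE)
    cat(sprintf("Pairwise tests: %d (BH-corrected within metric)\n",
                nrow(x$pairwise)))
  }
  invisible(x)
}
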