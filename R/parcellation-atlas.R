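# ROI-level machinery: PCA region time courses, fractional peak
# displacement, mean neighbor correlation, leadfield-influence accounting
# and the influence-driven atlas reduction (proportional ROI-count
# allocation + greedy merging of weak adjacent ROIs).

#' PCA time course per ROI
#'
#' Per ROI, dipole time courses are mean-centered over time and projected
#' onto their first principal direction, giving one representative time
#' course per ROI plus the unit loading vector (sign convention: sum of
#' loadings positive) and the fraction of within-ROI variance explained.
#'
#' @param est a \code{source_estimate} (or dipoles x samples matrix).
#' @param atlas an \code{atlas} covering the source space.
#' @return an object of class \code{roi_timecourses}: \code{data}
#'   (ROIs x samples), \code{mixing_columns} (list of per-ROI loading
#'   vectors), \code{explained_variance_fraction}.
#' @export
roi_timecourse_pca <- function(est, atlas) {
  s <- if (inherits(est, "source_estimate")) est$data else as.matrix(est)
  if (length(atlas$dipole_roi) != nrow(s))
    stop("atlas does not match the source space", call. = FALSE)
  if (ncol(s) < 2) stop("need at least 2 samples for PCA", call. = FALSE)
  n_rois <- length(atlas$roi_cluster)
  tc <- matrix(0, n_rois, ncol(s))
  mixing <- vector("list", n_rois)
  evf <- numeric(n_rois)
  for (roi in seq_len(n_rois)) {
    idx <- which(atlas$dipole_roi == roi)
    block <- s[idx, , drop = FALSE]
    centered <- block - rowMeans(block)
    if (length(idx) == 1L) {
      mixing[[roi]] <- 1
      tc[roi, ] <- centered
      evf[roi] <- 1
      next
    }
    sv <- svd(centered)
    u1 <- pc_sign(sv$u[, 1])
    mixing[[roi]] <- u1
    tc[roi, ] <- drop(crossprod(u1, centered))
    tot <- sum(sv$d^2)
    evf[roi] <- if (tot > 0) sv$d[1]^2 / tot else 1
  }
  structure(list(data = tc, mixing_columns = mixing,
                 explained_variance_fraction = evf),
            class = "roi_timecourses")
}

#' Fractional peak activity displacement (fPAD)
#'
#' Per ROI, the fraction of member dipoles whose point-spread function
#' attains its (absolute-value) maximum outside the ROI. A zero-PAD operator
#' has zero fPAD for every atlas.
#'
#' @param R a \code{resolution_matrix} (or square matrix).
#' @param atlas an \code{atlas}.
#' @return list: \code{per_roi} (fraction in [0, 1] per ROI),
#'   \code{mean_over_rois}, \code{mean_over_dipoles}, \code{n_undefined}
#'   (all-zero PSF columns, excluded).
#' @export
fpad <- function(R, atlas) {
  m <- res_mat(R)
  if (length(atlas$dipole_roi) != ncol(m))
    stop("atlas does not match the resolution matrix", call. = FALSE)
  a <- abs(m)
  peak_roi <- vapply(seq_len(ncol(a)), function(i) {
    col <- a[, i]
    if (all(col == 0)) return(NA_integer_)
    atlas$dipole_roi[which.max(col)]
  }, integer(1))
  outside <- peak_roi != atlas$dipole_roi
  per_roi <- vapply(seq_along(atlas$roi_cluster), function(roi) {
    idx <- which(atlas$dipole_roi == roi)
    vals <- outside[idx]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  list(per_roi = per_roi,
       mean_over_rois = mean(per_roi, na.rm = TRUE),
       mean_over_dipoles = mean(outside, na.rm = TRUE),
       n_undefined = sum(is.na(peak_roi)))
}

#' Mean neighbor correlation (mNC)
#'
#' Zero-lag Pearson correlation between the time courses of each pair of
#' adjacent ROIs, averaged (signed) over all adjacent pairs. High mNC at the
#' ROI level is the parcellated proxy for spatial leakage.
#'
#' @param tc a \code{roi_timecourses} (or ROIs x samples matrix).
#' @param atlas an \code{atlas} providing \code{roi_adjacency}.
#' @param absolute average \code{|r|} instead of signed r (default FALSE).
#' @return list: \code{mnc}, \code{pairs} (data.frame roi_a, roi_b, r),
#'   \code{n_excluded} (pairs with a constant time course).
#' @export
mean_neighbor_correlation <- function(tc, atlas, absolute = FALSE) {
  x <- if (inherits(tc, "roi_timecourses")) tc$data else as.matrix(tc)
  adj <- atlas$roi_adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("atlas has no adjacent ROI pairs", call. = FALSE)
  r <- vapply(seq_len(nrow(idx)), function(k)
    safe_cor(x[idx[k, 1], ], x[idx[k, 2], ]), numeric(1))
  vals <- if (absolute) abs(r) else r
  list(mnc = mean(vals, na.rm = TRUE),
       pairs = data.frame(roi_a = idx[, 1], roi_b = idx[, 2], r = r),
       n_excluded = sum(is.na(r)))
}

#' Leadfield influence of each ROI
#'
#' \code{||L_roi|| = sum over member dipoles of ||L_j||}: the summed
#' leadfield column norms quantify how strongly a ROI drives the sensors.
#' When several leadfields are supplied (a list), column norms are averaged
#' across them before summing.
#'
#' @param leadfield a \code{leadfield} or list of them (same source space).
#' @param atlas an \code{atlas}.
#' @return per-ROI influence (named numeric).
#' @export
roi_influence <- function(leadfield, atlas) {
  cn <- if (inherits(leadfield, "leadfield")) {
    leadfield$column_norms
  } else {
    rowMeans(vapply(leadfield, function(lf) lf$column_norms,
                    numeric(length(leadfield[[1]]$column_norms))))
  }
  if (length(cn) != length(atlas$dipole_roi))
    stop("leadfield does not match atlas", call. = FALSE)
  infl <- vapply(seq_along(atlas$roi_cluster), function(roi)
    sum(cn[atlas$dipole_roi == roi]), numeric(1))
  names(infl) <- atlas$names %||% paste0("ROI_", seq_along(infl))
  infl
}

#' Leadfield influence of each ROI cluster
#'
#' Sum of member-ROI influences per cluster (additivity of the influence).
#'
#' @param roi_infl per-ROI influence from \code{\link{roi_influence}}.
#' @param atlas an \code{atlas}.
#' @return per-cluster influence.
#' @export
cluster_influence <- function(roi_infl, atlas) {
  cl <- sort(unique(atlas$roi_cluster))
  out <- vapply(cl, function(k) sum(roi_infl[atlas$roi_cluster == k]),
                numeric(1))
  names(out) <- paste0("cluster_", cl)
  out
}

#' Allocate ROI counts to clusters proportional to influence
#'
#' Largest-remainder apportionment of \code{target_total} ROI slots across
#' clusters proportional to cluster influence, with a floor of one ROI per
#' cluster and a cap at each cluster's current ROI count. Counts sum exactly
#' to the target.
#'
#' @param cluster_infl per-cluster influence (positive).
#' @param target_total total ROI count after reduction (>= cluster count).
#' @param current_counts per-cluster current ROI counts (caps); defaults to
#'   unbounded.
#' @return integer per-cluster allocation summing to \code{target_total}.
#' @export
allocate_roi_counts <- function(cluster_infl, target_total,
                                current_counts = NULL) {
  k <- length(cluster_infl)
  if (target_total < k)
    stop("target_total must be >= number of clusters", call. = FALSE)
  if (is.null(current_counts)) current_counts <- rep(.Machine$integer.max, k)
  if (target_total > sum(pmin(current_counts, .Machine$integer.max)))
    stop("target_total exceeds the available ROI count", call. = FALSE)
  if (any(cluster_infl <= 0)) stop("influences must be positive",
                                   call. = FALSE)
  quota <- target_total * cluster_infl / sum(cluster_infl)
  counts <- pmax(1L, pmin(current_counts, as.integer(floor(quota))))
  # distribute (or claw back) the remainder by largest (smallest) residual
  repeat {
    deficit <- target_total - sum(counts)
    if (deficit == 0) break
    resid <- quota - counts
    if (deficit > 0) {
      cand <- which(counts < current_counts)
      if (length(cand) == 0) stop("allocation infeasible", call. = FALSE)
      pick <- cand[order(-resid[cand], cand)][1]
      counts[pick] <- counts[pick] + 1L
    } else {
      cand <- which(counts > 1L)
      if (length(cand) == 0) stop("allocation infeasible", call. = FALSE)
      pick <- cand[order(resid[cand], cand)][1]
      counts[pick] <- counts[pick] - 1L
    }
  }
  as.integer(counts)
}

#' Greedy influence-balancing ROI merge
#'
#' Within each cluster, repeatedly merges the lowest-influence ROI with its
#' lowest-influence adjacent ROI in the same cluster until the allocated
#' count is reached. An automated stand-in for anatomy-guided merging: it
#' pursues a more uniform distribution of ROI influence and does not
#' replicate any published manually merged atlas.
#'
#' @param atlas an \code{atlas}.
#' @param leadfield a \code{leadfield} (or list averaged as in
#'   \code{\link{roi_influence}}).
#' @param allocated_counts per-cluster targets from
#'   \code{\link{allocate_roi_counts}} (clusters in sorted id order).
#' @return list: \code{atlas} (reduced; ROI ids renumbered contiguously) and
#'   \code{plan} (an \code{atlas_reduction_plan}: influences before/after,
#'   allocated counts, merge ledger).
#' @export
greedy_merge <- function(atlas, leadfield, allocated_counts) {
  infl <- roi_influence(leadfield, atlas)
  clusters <- sort(unique(atlas$roi_cluster))
  if (length(allocated_counts) != length(clusters))
    stop("one allocated count per cluster required", call. = FALSE)
  # working state: ROI membership sets, influence, adjacency, cluster id
  n_rois <- length(atlas$roi_cluster)
  members <- lapply(seq_len(n_rois), function(r) which(atlas$dipole_roi == r))
  adj <- atlas$roi_adjacency
  alive <- rep(TRUE, n_rois)
  roi_cl <- atlas$roi_cluster
  w <- infl
  merges <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    target <- allocated_counts[ci]
    repeat {
      in_cl <- which(alive & roi_cl == cl)
      if (length(in_cl) <= target) break
      # weakest ROI with an in-cluster neighbor
      ord <- in_cl[order(w[in_cl], in_cl)]
      pair <- NULL
      for (a in ord) {
        nb <- which(adj[a, ] & alive & roi_cl == cl)
        if (length(nb) > 0) {
          b <- nb[order(w[nb], nb)][1]
          pair <- c(a, b)
          break
        }
      }
      if (is.null(pair))
        stop(sprintf("cluster %d: ROIs disconnected, cannot reach count %d",
                     cl, target), call. = FALSE)
      a <- pair[1]; b <- pair[2]
      keep <- min(a, b); drop <- max(a, b)
      members[[keep]] <- sort(c(members[[keep]], members[[drop]]))
      w[keep] <- w[keep] + w[drop]
      adj[keep, ] <- adj[keep, ] | adj[drop, ]
      adj[, keep] <- adj[, keep] | adj[, drop]
      adj[keep, keep] <- FALSE
      alive[drop] <- FALSE
      merges[[length(merges) + 1L]] <-
        list(cluster = cl, kept = keep, absorbed = drop)
    }
  }
  surv <- which(alive)
  new_id <- integer(n_rois)
  new_id[surv] <- seq_along(surv)
  dipole_roi <- integer(length(atlas$dipole_roi))
  for (r in surv) dipole_roi[members[[r]]] <- new_id[r]
  reduced <- structure(list(dipole_roi = dipole_roi,
                            roi_cluster = roi_cl[surv],
                            roi_adjacency = adj[surv, surv, drop = FALSE],
                            names = paste0("ROI_", seq_along(surv))),
                       class = "atlas")
  plan <- structure(list(roi_influence = infl,
                         cluster_influence = cluster_influence(infl, atlas),
                         allocated_counts = allocated_counts,
                         merged_influence = w[surv],
                         merges = merges),
                    class = "atlas_reduction_plan")
  list(atlas = reduced, plan = plan)
}

#' Reduce an atlas to a target ROI count
#'
#' Convenience wrapper: influence accounting, proportional allocation and
#' greedy merging in one call.
#'
#' @param atlas an \code{atlas}.
#' @param leadfield a \code{leadfield} or list of leadfields.
#' @param target_total total ROI count after reduction.
#' @return as \code{\link{greedy_merge}}.
#' @export
reduce_atlas <- function(atlas, leadfield, target_total) {
  infl <- roi_influence(leadfield, atlas)
  cl_infl <- cluster_influence(infl, atlas)
  current <- as.integer(table(factor(atlas$roi_cluster,
                                     levels = sort(unique(atlas$roi_cluster)))))
  counts <- allocate_roi_counts(cl_infl, target_total, current)
  greedy_merge(atlas, leadfield, counts)
}

#' Read / write atlas label tables
#'
#' Plain TSV with columns \code{dipole_id}, \code{roi_id},
#' \code{cluster_id}.
#'
#' @param atlas an \code{atlas}.
#' @param path file path.
#' @return \code{write_atlas_tsv}: the path, invisibly.
#'   \code{read_atlas_tsv}: an \code{atlas} (adjacency absent unless
#'   recomputed against a head model).
#' @export
write_atlas_tsv <- function(atlas, path) {
  df <- data.frame(dipole_id = seq_along(atlas$dipole_roi),
                   roi_id = atlas$dipole_roi,
                   cluster_id = atlas$roi_cluster[atlas$dipole_roi])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("dipole_id", "roi_id", "cluster_id")
  if (!all(need %in% names(df)))
    stop(sprintf("atlas TSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[order(df$dipole_id), ]
  rois <- sort(unique(df$roi_id))
  if (!identical(rois, seq_along(rois)))
    stop("roi_id values must be 1..n_rois", call. = FALSE)
  roi_cluster <- vapply(rois, function(r)
    unique(df$cluster_id[df$roi_id == r])[1], numeric(1))
  structure(list(dipole_roi = as.integer(df$roi_id),
                 roi_cluster = as.integer(roi_cluster),
                 roi_adjacency = NULL,
                 names = paste0("ROI_", rois)),
            class = "atlas")
}
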