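test_that("ROI PCA time courses: rank-1, singleton and hand-eigendecomposed ROIs", {
  w <- small_world()
  atlas <- build_synthetic_atlas(w$head, n_rois = 6, n_clusters = 2,
                                 seed = 2)
  # rank-1 ROI: PC1 explains everything, time course tracks the shared signal
  s <- matrix(rnorm(60 * 200), 60)
  idx <- which(atlas$dipole_roi == 1)
  shared <- rnorm(200)
  s[idx, ] <- outer(seq_along(idx), shared)  # scaled copies of one course
  tc <- roi_timecourse_pca(s, atlas)
  expect_equal(tc$explained_variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(abs(cor(tc$data[1, ], shared)), 1, tolerance = 1e-12)
  # loading vectors unit norm; sign convention: sum of loadings positive
  for (v in tc$mixing_columns) {
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    expect_gte(sum(v), 0)
  }

  # singleton ROI equals the centered dipole course
  a1 <- build_synthetic_atlas(w$head, n_rois = 60, n_clusters = 3, seed = 1)
  tc1 <- roi_timecourse_pca(s, a1)
  d <- which(a1$dipole_roi == 4)
  expect_equal(tc1$data[4, ], s[d, ] - mean(s[d, ]), tolerance = 1e-12)

  # 2-dipole ROI with covariance [[2,1],[1,2]]: loading (1,1)/sqrt(2),
  # explained fraction 3/4 -- checked against the analytic eigensystem by
  # constructing exact-covariance data
  t_len <- 400
  raw <- scale(matrix(rnorm(t_len * 2), t_len), scale = FALSE)
  base <- qr.Q(qr(raw))[, 1:2] * sqrt(t_len - 1)  # zero-mean orthonormal
  chol_u <- chol(matrix(c(2, 1, 1, 2), 2))
  two <- t(base %*% chol_u)  # 2 x T, sample covariance exactly [[2,1],[1,2]]
  atlas2 <- list(dipole_roi = c(1, 1), roi_cluster = 1L,
                 roi_adjacency = matrix(FALSE, 1, 1), names = "ROI_1")
  class(atlas2) <- "atlas"
  tc2 <- roi_timecourse_pca(two, atlas2)
  expect_equal(abs(tc2$mixing_columns[[1]]), rep(1 / sqrt(2), 2),
               tolerance = 1e-8)
  expect_equal(tc2$explained_variance_fraction[1], 3 / 4, tolerance = 1e-8)
})

test_that("fPAD counts out-of-ROI peaks and is zero for identity resolution", {
  w <- small_world()
  atlas <- build_synthetic_atlas(w$head, n_rois = 6, n_clusters = 2,
                                 seed = 2)
  n <- length(atlas$dipole_roi)
  f0 <- fpad(diag(n), atlas)
  expect_equal(f0$per_roi, rep(0, 6))
  expect_equal(f0$mean_over_rois, 0)

  # hand-built: ROI with one inside peak and one outside peak -> 0.5
  roi1 <- which(atlas$dipole_roi == 1)[1:2]
  other <- which(atlas$dipole_roi != 1)[1]
  R <- diag(n)
  R[, roi1[2]] <- 0
  R[other, roi1[2]] <- 1  # dipole 2 of ROI 1 peaks outside
  f <- fpad(R, atlas)
  n_roi1 <- sum(atlas$dipole_roi == 1)
  expect_equal(f$per_roi[1], 1 / n_roi1)

  # degenerate one-dipole-per-ROI atlas: fPAD is the indicator of PAD > 0
  a1 <- build_synthetic_atlas(w$head, n_rois = n, n_clusters = 3, seed = 1)
  op <- make_inverse_operator(w$lf, "mne")
  R_mne <- resolution_matrix(op, w$lf)
  p <- pad(R_mne, w$head$dipole_positions)
  f1 <- fpad(R_mne, a1)
  expect_equal(f1$per_roi[a1$dipole_roi], as.numeric(p > 0))
})

test_that("mean neighbor correlation matches constructed correlations", {
  w <- small_world()
  atlas <- build_synthetic_atlas(w$head, n_rois = 6, n_clusters = 2,
                                 seed = 2)
  t_len <- 7680
  # all ROIs share one course: mNC = 1
  one <- matrix(rep(rnorm(t_len), 6), 6, byrow = TRUE)
  expect_equal(mean_neighbor_correlation(one, atlas)$mnc, 1,
               tolerance = 1e-12)
  # independent courses: mNC at the null scale
  set.seed(4)
  ind <- matrix(rnorm(6 * t_len), 6)
  n_pairs <- sum(atlas$roi_adjacency) / 2
  expect_lt(abs(mean_neighbor_correlation(ind, atlas)$mnc),
            3 / sqrt(t_len * n_pairs) + 3 / sqrt(t_len))
  # constructed correlation 0.5 between all neighbors via a common part
  set.seed(5)
  common <- rnorm(t_len)
  mixed <- t(vapply(1:6, function(i)
    common / sqrt(2) + rnorm(t_len) / sqrt(2), numeric(t_len)))
  got <- mean_neighbor_correlation(mixed, atlas)$mnc
  expect_equal(got, 0.5, tolerance = 0.05)
  # constant course excluded and counted
  mixed[1, ] <- 1
  res <- mean_neighbor_correlation(mixed, atlas)
  expect_gt(res$n_excluded, 0)
})

test_that("ROI and cluster influences are additive in the leadfield column norms", {
  w <- small_world()
  atlas <- build_synthetic_atlas(w$head, n_rois = 6, n_clusters = 2,
                                 seed = 2)
  infl <- roi_influence(w$lf, atlas)
  # direct hand-summed check
  for (roi in 1:6)
    expect_equal(unname(infl[roi]),
                 sum(w$lf$column_norms[atlas$dipole_roi == roi]))
  cl <- cluster_influence(infl, atlas)
  expect_equal(sum(cl), sum(infl), tolerance = 1e-12)
  expect_equal(unname(cl[1]), sum(infl[atlas$roi_cluster == 1]))
  # singleton ROI influence equals its column norm
  a1 <- build_synthetic_atlas(w$head, n_rois = 60, n_clusters = 3, seed = 1)
  i1 <- roi_influence(w$lf, a1)
  expect_equal(unname(i1[a1$dipole_roi]), w$lf$column_norms,
               tolerance = 1e-12)
  # multi-leadfield influence averages column norms across subjects
  lf2 <- new_leadfield(3 * w$lf$matrix)
  i_avg <- roi_influence(list(w$lf, lf2), atlas)
  expect_equal(unname(i_avg), unname(infl) * 2, tolerance = 1e-12)
})

test_that("ROI count allocation is exact, proportional and scale-invariant", {
  expect_identical(allocate_roi_counts(c(50, 30, 20), 10), c(5L, 3L, 2L))
  expect_identical(allocate_roi_counts(c(70, 20, 10), 5), c(3L, 1L, 1L))
  # equal influences, divisible target: equal counts
  expect_identical(allocate_roi_counts(c(1, 1, 1, 1), 8), rep(2L, 4))
  # scale invariance
  expect_identical(allocate_roi_counts(c(50, 30, 20) * 1e6, 10),
                   allocate_roi_counts(c(50, 30, 20), 10))
  # exact sum under awkward quotas, floor of 1 and caps
  set.seed(11)
  for (rep in 1:20) {
    infl <- runif(5, 0.01, 1)
    caps <- sample(2:6, 5, replace = TRUE)
    target <- sample(5:sum(caps), 1)
    got <- allocate_roi_counts(infl, target, caps)
    expect_identical(sum(got), as.integer(target))
    expect_true(all(got >= 1L & got <= caps))
  }
  expect_error(allocate_roi_counts(c(1, 1), 1), ">= number of clusters")
  expect_error(allocate_roi_counts(c(1, 1), 5, current_counts = c(2, 2)),
               "exceeds")
})

test_that("greedy merging reaches allocated counts and balances influence", {
  # 3 chain-adjacent ROIs with influences (1, 1, 8), target 2: the two
  # weakest merge
  adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 1] <- TRUE
  adj[2, 3] <- adj[3, 2] <- TRUE
  atlas <- structure(list(dipole_roi = c(1L, 2L, 3L, 3L),
                          roi_cluster = c(1L, 1L, 1L),
                          roi_adjacency = adj,
                          names = paste0("ROI_", 1:3)),
                     class = "atlas")
  lf <- new_leadfield(rbind(c(1, 1, 4, 4), c(0, 0, 4, 4)))
  infl <- roi_influence(lf, atlas)
  expect_equal(unname(infl), c(1, 1, 2 * sqrt(32)), tolerance = 1e-12)
  out <- greedy_merge(atlas, lf, allocated_counts = 2L)
  expect_length(out$atlas$roi_cluster, 2)
  expect_equal(unname(out$plan$merged_influence),
               c(2, 2 * sqrt(32)), tolerance = 1e-12)
  expect_length(out$plan$merges, 1)
  # dipole labels remain a partition and total influence is conserved
  expect_identical(sort(unique(out$atlas$dipole_roi)), 1:2)
  expect_equal(sum(out$plan$merged_influence), sum(infl), tolerance = 1e-12)

  # counts equal to current counts: unchanged, no merges
  same <- greedy_merge(atlas, lf, allocated_counts = 3L)
  expect_length(same$plan$merges, 0)
  expect_identical(same$atlas$dipole_roi, atlas$dipole_roi)

  # relative spread (coefficient of variation) of ROI influences never
  # increases across seeded reductions: the uniformity objective
  for (k in 1:10) {
    cfg <- small_config(seed = 400 + k)
    head <- build_spherical_head(cfg)
    lfk <- compute_leadfield(head)
    a <- build_synthetic_atlas(head, n_rois = 12, n_clusters = 3,
                               seed = 500 + k)
    red <- reduce_atlas(a, lfk, target_total = 6)
    infl_b <- roi_influence(lfk, a)
    cv_before <- sd(infl_b) / mean(infl_b)
    cv_after <- sd(red$plan$merged_influence) /
      mean(red$plan$merged_influence)
    expect_lte(cv_after, cv_before + 1e-15)
  }
})

test_that("atlas TSV round-trips and rejects malformed tables", {
  w <- small_world()
  atlas <- build_synthetic_atlas(w$head, n_rois = 6, n_clusters = 2,
                                 seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_atlas_tsv(atlas, path)
  back <- read_atlas_tsv(path)
  expect_identical(back$dipole_roi, atlas$dipole_roi)
  expect_identical(back$roi_cluster, atlas$roi_cluster)
  bad <- tempfile(fileext = ".tsv")
  writeLines("dipole_id\twrong\n1\t2", bad)
  expect_error(read_atlas_tsv(bad), "columns")
})
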