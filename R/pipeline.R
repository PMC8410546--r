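# End-to-end orchestration: simulate (or load) data, sweep algorithms and
# predicted SNRs, compute every metric, run the group statistics, and emit a
# machine-readable report directory.

#' Evaluation configuration
#'
#' @param sim a \code{\link{simulation_config}} for the synthetic data.
#' @param algorithms algorithm subset (default all six).
#' @param snr_db regularization SNR for the headline results (default 2.5).
#' @param snr_sweep_db predicted-SNR sweep (default -10..10 dB in 7 steps).
#' @param n_subjects number of independent seeded simulations standing in
#'   for the subject cohort (default 11).
#' @param folds sensor cross-validation fold count; NULL scales the
#'   27-fold / 274-channel design to the array
#'   (\code{\link{default_fold_count}}).
#' @param n_rois,n_clusters synthetic atlas size (default 20 ROIs in 5
#'   clusters).
#' @param atlas_target reduced-atlas ROI count (default 12).
#' @param sigma2_grid robustness noise grid.
#' @param seed master seed; every stage derives its own seed from it.
#' @param run_robustness,run_similarity,run_snr_sweep stage switches.
#' @return an object of class \code{evaluation_config}.
#' @export
evaluation_config <- function(sim = simulation_config(),
                              algorithms = algorithm_names(),
                              snr_db = 2.5,
                              snr_sweep_db = c(-10, -5, -2.5, 0, 2.5, 5, 10),
                              n_subjects = 11, folds = NULL,
                              n_rois = 20, n_clusters = 5,
                              atlas_target = 12,
                              sigma2_grid = c(0, 0.1, 0.25, 0.5, 1, 2, 4),
                              seed = 1L,
                              run_robustness = TRUE,
                              run_similarity = TRUE,
                              run_snr_sweep = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  algorithms <- match.arg(algorithms, algorithm_names(), several.ok = TRUE)
  if (length(algorithms) == 0) stop("no algorithms selected", call. = FALSE)
  structure(list(sim = sim, algorithms = algorithms, snr_db = snr_db,
                 snr_sweep_db = snr_sweep_db,
                 n_subjects = as.integer(n_subjects), folds = folds,
                 n_rois = as.integer(n_rois),
                 n_clusters = as.integer(n_clusters),
                 atlas_target = as.integer(atlas_target),
                 sigma2_grid = sigma2_grid, seed = as.integer(seed),
                 run_robustness = isTRUE(run_robustness),
                 run_similarity = isTRUE(run_similarity),
                 run_snr_sweep = isTRUE(run_snr_sweep)),
            class = "evaluation_config")
}

# Deterministic per-(subject, stage) seed derived from the master seed,
# kept below 2^31.
derive_seed <- function(master, subject, stage) {
  (as.integer(master) * 1009L + subject * 101L + stage) %% 2147483647L
}

#' Run the full evaluation
#'
#' For each simulated subject (an independent seeded simulation on a shared
#' head geometry): build the leadfield, simulate resting and empty-room
#' recordings, construct every requested inverse operator at the headline
#' SNR, and compute resolution metrics (PAD/SEPS/SECT), cross-validated
#' variance explained on resting and empty-room data with their ratio,
#' parcellated metrics (parcellated r2, fPAD, mNC), and optionally
#' robustness curves and the between-algorithm similarity matrix. Metric
#' tables across subjects then feed the Friedman / Wilcoxon / BH battery.
#'
#' @param config an \code{\link{evaluation_config}}.
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV/JSON plus a run manifest.
#' @return an object of class \code{evaluation_report}: \code{metrics}
#'   (long data.frame subject/algorithm/metric/value), \code{tables}
#'   (named list of subjects x algorithms matrices), \code{stats}
#'   (a \code{stats_report}), \code{similarity} (median similarity matrix
#'   and its dendrogram, if run), \code{config}.
#' @export
run_evaluation <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "evaluation_config"))
  sim0 <- config$sim
  head <- build_spherical_head(sim0)
  lf <- compute_leadfield(head)
  atlas <- build_synthetic_atlas(head, config$n_rois, config$n_clusters,
                                 seed = config$seed)
  folds <- config$folds %||% default_fold_count(sim0$n_sensors)
  pos <- head$dipole_positions
  rows <- list()
  sim_mats <- list()
  for (subj in seq_len(config$n_subjects)) {
    sim <- sim0
    sim$seed <- derive_seed(config$seed, subj, 1L)
    sources <- simulate_sources(head, sim)
    rec <- simulate_recording(lf, sources, snr_db = sim0$snr_db,
                              seed = derive_seed(config$seed, subj, 2L))
    er <- simulate_empty_room(sim0$n_sensors, sim0$duration_s, sim0$fs,
                              seed = derive_seed(config$seed, subj, 3L))
    part <- partition_sensors(sim0$n_sensors, folds,
                              seed = derive_seed(config$seed, subj, 4L))
    ests <- list()
    for (alg in config$algorithms) {
      spec <- algorithm_spec(alg, snr_db = config$snr_db)
      op <- build_operator(spec, lf, data = rec$data)
      res <- resolution_metrics(op, lf, pos)
      cv <- cross_validated_r2(rec, lf, spec, part)
      cv_er <- cross_validated_r2(er, lf, spec, part)
      cv_parc <- parcellated_cross_validated_r2(rec, lf, spec, part, atlas)
      R <- resolution_matrix(op, lf)
      fp <- fpad(R, atlas)
      est <- apply_inverse(op, rec)
      tc <- roi_timecourse_pca(est, atlas)
      mnc <- mean_neighbor_correlation(tc, atlas)
      vals <- c(pad = res$mean_pad, seps = res$mean_seps,
                sect = res$mean_sect,
                r2_cv = cv$r2, r2_er = cv_er$r2,
                ve_ratio = ve_ratio(cv, cv_er),
                r2_cv_parcellated = cv_parc$r2,
                fpad = fp$mean_over_rois, mnc = mnc$mnc)
      if (config$run_robustness) {
        rb <- noise_robustness(rec, lf, spec,
                               sigma2_grid = config$sigma2_grid,
                               seed = derive_seed(config$seed, subj, 5L))
        vals <- c(vals, robustness_std = rb$std_across_levels)
      }
      ests[[alg]] <- est
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subj, algorithm = alg,
                   metric = names(vals), value = unname(vals))
    }
    if (config$run_similarity && length(ests) >= 2)
      sim_mats[[subj]] <- similarity_matrix(ests)$matrix
  }
  metrics <- do.call(rbind, rows)
  tables <- metric_tables(metrics, config$algorithms)
  stats_rep <- build_stats_report(tables)
  similarity <- NULL
  if (length(sim_mats) > 0) {
    med <- apply(simplify2array(sim_mats), c(1, 2), stats::median)
    dimnames(med) <- dimnames(sim_mats[[1]])
    sim_obj <- structure(list(matrix = med, labels = rownames(med)),
                         class = "similarity_matrix")
    similarity <- list(median = med,
                       dendrogram = normalized_cuts_dendrogram(sim_obj))
  }
  report <- structure(list(metrics = metrics, tables = tables,
                           stats = stats_rep, similarity = similarity,
                           config = config),
                      class = "evaluation_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Long metric frame -> named list of subjects x algorithms matrices.
metric_tables <- function(metrics, algorithms) {
  out <- list()
  subjects <- sort(unique(metrics$subject))
  for (metric in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == metric, ]
    m <- matrix(NA_real_, length(subjects), length(algorithms),
                dimnames = list(subjects, algorithms))
    m[cbind(match(sub$subject, subjects),
            match(sub$algorithm, algorithms))] <- sub$value
    out[[metric]] <- m
  }
  out
}

# Write all report tables as TSV/JSON plus a manifest.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$stats$friedman,
                     file.path(out_dir, "friedman.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$stats$pairwise,
                     file.path(out_dir, "pairwise.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$similarity)) {
    utils::write.table(report$similarity$median,
                       file.path(out_dir, "similarity_median.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(report$similarity$dendrogram,
                         file.path(out_dir, "dendrogram.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest <- list(seed = report$config$seed,
                   algorithms = report$config$algorithms,
                   n_subjects = report$config$n_subjects,
                   snr_db = report$config$snr_db,
                   n_sensors = report$config$sim$n_sensors,
                   n_dipoles = report$config$sim$n_dipoles,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Plain-text matrix / recording I/O
#'
#' Leadfields and recordings serialize to headerless TSV matrices; the
#' recording carries its sampling rate and kind in a JSON sidecar written
#' next to the matrix.
#'
#' @param leadfield a \code{leadfield}.
#' @param path file path.
#' @return the path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
write_leadfield_tsv <- function(leadfield, path) {
  utils::write.table(leadfield$matrix, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield_tsv
#' @export
read_leadfield_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  lf <- new_leadfield(m)
  zero <- which(lf$column_norms == 0)
  if (length(zero) > 0)
    stop(sprintf("leadfield has an all-zero column at dipole %d", zero[1]),
         call. = FALSE)
  lf
}

#' @rdname write_leadfield_tsv
#' @param rec a \code{recording}.
#' @export
write_recording_tsv <- function(rec, path) {
  utils::write.table(rec$data, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, kind = rec$kind, seed = rec$seed),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_leadfield_tsv
#' @export
read_recording_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (ncol(m) < 2) stop("recording needs at least 2 samples", call. = FALSE)
  if (any(apply(m, 1, stats::var) <= 0))
    stop("recording has a zero-variance channel", call. = FALSE)
  structure(list(data = m, fs = meta$fs, kind = meta$kind,
                 seed = as.integer(meta$seed %||% NA_integer_)),
            class = "recording")
}

#' Load and validate external pipeline inputs
#'
#' Replaces the synthetic inputs with user-supplied files: a leadfield TSV
#' matrix, recording TSVs (with JSON sidecars) and an atlas label TSV. All
#' structural invariants are enforced at load (no zero leadfield columns,
#' atlas covering the source space, matching channel counts).
#'
#' @param leadfield_path leadfield TSV path.
#' @param resting_path,empty_room_path recording TSV paths
#'   (\code{empty_room_path} optional).
#' @param atlas_path optional atlas label TSV.
#' @return list with \code{leadfield}, \code{resting}, \code{empty_room},
#'   \code{atlas}.
#' @export
load_external_inputs <- function(leadfield_path, resting_path,
                                 empty_room_path = NULL, atlas_path = NULL) {
  lf <- read_leadfield_tsv(leadfield_path)
  rec <- read_recording_tsv(resting_path)
  if (nrow(rec$data) != nrow(lf$matrix))
    stop("recording channel count does not match the leadfield",
         call. = FALSE)
  er <- NULL
  if (!is.null(empty_room_path)) {
    er <- read_recording_tsv(empty_room_path)
    if (nrow(er$data) != nrow(lf$matrix))
      stop("empty-room channel count does not match the leadfield",
           call. = FALSE)
  }
  atlas <- NULL
  if (!is.null(atlas_path)) {
    atlas <- read_atlas_tsv(atlas_path)
    if (length(atlas$dipole_roi) != ncol(lf$matrix))
      stop("atlas does not cover the leadfield source space", call. = FALSE)
  }
  list(leadfield = lf, resting = rec, empty_room = er, atlas = atlas)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %d subjects x %d algorithms, %d metrics\n",
              x$config$n_subjects, length(x$config$algorithms),
              length(x$tables)))
  invisible(x)
}
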