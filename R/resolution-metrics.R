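# Resolution-matrix metrics.  R = Phi L relates true to estimated source
# activity; column j is the point-spread function (PSF) of dipole j, row i
# the cross-talk function (CTF) of dipole i.  PAD measures peak
# displacement, SEPS/SECT measure the PSF-/CTF-weighted RMS spatial extent
# of leakage.

#' Resolution matrix
#'
#' @param op an \code{inverse_operator}.
#' @param leadfield a \code{leadfield}.
#' @return an object of class \code{resolution_matrix}: \code{matrix}
#'   (dipoles x dipoles, \code{Phi \%*\% L}), \code{algorithm}.
#' @export
resolution_matrix <- function(op, leadfield) {
  if (ncol(op$filters) != nrow(leadfield$matrix))
    stop("operator/leadfield dimension mismatch", call. = FALSE)
  structure(list(matrix = op$filters %*% leadfield$matrix,
                 algorithm = op$algorithm),
            class = "resolution_matrix")
}

res_mat <- function(R) {
  if (inherits(R, "resolution_matrix")) R$matrix else as.matrix(R)
}

#' Peak activity displacement (PAD)
#'
#' For each dipole i, the Euclidean distance from dipole i to the dipole at
#' which its point-spread function attains its (absolute-value) maximum.
#' Ties break to the smallest dipole index; an all-zero PSF column is
#' flagged undefined (NA) and excluded from summaries.
#'
#' @param R a \code{resolution_matrix} (or plain square matrix).
#' @param positions dipole positions, one row per dipole, meters.
#' @param absolute use \code{|PSF|} in the argmax (default TRUE); a
#'   sign-flipped peak is still a peak.
#' @return per-dipole PAD in meters (NA where undefined).
#' @export
pad <- function(R, positions, absolute = TRUE) {
  m <- res_mat(R)
  positions <- as.matrix(positions)
  if (nrow(positions) != ncol(m))
    stop("positions must have one row per dipole", call. = FALSE)
  a <- if (absolute) abs(m) else m
  vapply(seq_len(ncol(a)), function(i) {
    col <- a[, i]
    if (all(col == 0)) return(NA_real_)
    j <- which.max(col)  # ties -> smallest index
    sqrt(sum((positions[i, ] - positions[j, ])^2))
  }, numeric(1))
}

# Shared core for SEPS/SECT: weighted RMS distance with weights R^2 over
# columns (PSF) or rows (CTF).
spatial_extent <- function(m, positions, margin, sqrt_out = TRUE) {
  d2 <- distance_matrix(positions)^2
  w <- m^2
  if (margin == "col") {
    num <- colSums(w * d2)
    den <- colSums(w)
  } else {
    num <- rowSums(w * d2)
    den <- rowSums(w)
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  if (sqrt_out) sqrt(out) else out
}

#' Spatial extent of point spread (SEPS)
#'
#' PSF-weighted RMS distance from each seed dipole:
#' \code{SEPS_i = sqrt( sum_j R_ji^2 d(j,i)^2 / sum_j R_ji^2 )}. The square
#' root puts the metric in distance units (spatial-dispersion convention);
#' \code{sqrt_out = FALSE} returns the raw ratio.
#'
#' @inheritParams pad
#' @param sqrt_out apply the square root (default TRUE).
#' @return per-dipole SEPS in meters (NA where the PSF column is zero).
#' @export
seps <- function(R, positions, sqrt_out = TRUE) {
  m <- res_mat(R)
  positions <- as.matrix(positions)
  if (nrow(positions) != ncol(m))
    stop("positions must have one row per dipole", call. = FALSE)
  spatial_extent(m, positions, "col", sqrt_out)
}

#' Spatial extent of cross talk (SECT)
#'
#' CTF counterpart to \code{\link{seps}}: the same weighted RMS distance
#' computed over rows of the resolution matrix. Invariant to positive
#' rescaling of filter rows, hence identical for LCMV and UNGMV.
#'
#' @inheritParams seps
#' @return per-dipole SECT in meters (NA where the CTF row is zero).
#' @export
sect <- function(R, positions, sqrt_out = TRUE) {
  m <- res_mat(R)
  positions <- as.matrix(positions)
  if (nrow(positions) != ncol(m))
    stop("positions must have one row per dipole", call. = FALSE)
  spatial_extent(m, positions, "row", sqrt_out)
}

#' Resolution metrics for one operator
#'
#' Computes the resolution matrix and all three voxel-level metrics.
#'
#' @param op an \code{inverse_operator}.
#' @param leadfield a \code{leadfield}.
#' @param positions dipole positions (meters).
#' @return an object of class \code{resolution_result}: per-dipole
#'   \code{pad}, \code{seps}, \code{sect} (meters), their means over defined
#'   dipoles, undefined counts, and the algorithm id.
#' @export
resolution_metrics <- function(op, leadfield, positions) {
  R <- resolution_matrix(op, leadfield)
  p <- pad(R, positions)
  sp <- seps(R, positions)
  sc <- sect(R, positions)
  structure(list(pad = p, seps = sp, sect = sc,
                 mean_pad = mean(p, na.rm = TRUE),
                 mean_seps = mean(sp, na.rm = TRUE),
                 mean_sect = mean(sc, na.rm = TRUE),
                 n_undefined = sum(is.na(p) | is.na(sp) | is.na(sc)),
                 algorithm = op$algorithm),
            class = "resolution_result")
}

#' Summarize per-dipole resolution metrics
#'
#' Arithmetic means over dipoles, excluding undefined (NA) entries, plus the
#' per-dipole table for spatial maps.
#'
#' @param result a \code{resolution_result}.
#' @return list with \code{means} (named numeric) and \code{table}
#'   (data.frame: dipole_id, pad_m, seps_m, sect_m, algorithm).
#' @export
summarize_resolution <- function(result) {
  stopifnot(inherits(result, "resolution_result"))
  list(means = c(pad = mean(result$pad, na.rm = TRUE),
                 seps = mean(result$seps, na.rm = TRUE),
                 sect = mean(result$sect, na.rm = TRUE)),
       n_undefined = result$n_undefined,
       table = data.frame(dipole_id = seq_along(result$pad),
                          pad_m = result$pad, seps_m = result$seps,
                          sect_m = result$sect,
                          algorithm = result$algorithm))
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("Resolution metrics [%s]: mean PAD %.4g m, SEPS %.4g m, SECT %.4g m (%d undefined)\n",
              x$algorithm, x$mean_pad, x$mean_seps, x$mean_sect,
              x$n_undefined))
  invisible(x)
}
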