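# ROI time courses and per-scan functional-connectivity matrices.

#' Truncate scans to a common retained length
#'
#' To equalize degrees of freedom across scans, each scan contributes
#' segments of exactly `target` frames: scans with fewer retained frames are
#' dropped (with a warning), scans with at least `2 * target` frames
#' contribute two disjoint segments, all others contribute their first
#' `target` frames.
#'
#' @param scans list of [volume4d] (retained frames).
#' @param target segment length in frames (default 540).
#' @return list of [volume4d] segments; attribute `source` maps each segment
#'   back to its input scan index.
#' @export
truncate_to_common_length <- function(scans, target = 540L) {
  out <- list(); src <- integer(0)
  for (i in seq_along(scans)) {
    nt <- n_frames(scans[[i]])
    if (nt < target) {
      warning(sprintf("scan %d has %d < %d frames; dropped", i, nt, target))
      next
    }
    take <- function(idx) {
      v <- scans[[i]]
      volume4d(v$data[, , , idx, drop = FALSE], v$voxel_size_mm, v$tr_s,
               v$affine)
    }
    out[[length(out) + 1L]] <- take(seq_len(target))
    src <- c(src, i)
    if (nt >= 2L * target) {
      out[[length(out) + 1L]] <- take(seq(target + 1L, 2L * target))
      src <- c(src, i)
    }
  }
  attr(out, "source") <- src
  out
}

#' Regionally averaged time courses
#'
#' @param vol a [volume4d].
#' @param atlas a [roi_atlas] on the data grid.
#' @return N x T matrix (rows named by ROI label); ROIs with no voxels are
#'   excluded with a warning.
#' @export
roi_timecourses <- function(vol, atlas) {
  stopifnot_same_grid(dim(atlas$labels), dim(vol$data)[1:3], "atlas")
  d <- dim(vol$data)
  flat <- matrix(vol$data, prod(d[1:3]), d[4])
  lab <- as.integer(atlas$labels)
  rois <- atlas$table$label
  out <- matrix(NA_real_, length(rois), d[4])
  keep <- rep(TRUE, length(rois))
  for (i in seq_along(rois)) {
    idx <- which(lab == rois[i])
    if (!length(idx)) {
      warning("ROI ", rois[i], " has no voxels; excluded")
      keep[i] <- FALSE
      next
    }
    out[i, ] <- if (length(idx) == 1L) flat[idx, ]
                else colMeans(flat[idx, , drop = FALSE])
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- rois[keep]
  out
}

#' Per-scan Fisher-z FC matrix
#'
#' Pearson correlations between ROI time courses, clipped away from +/-1 and
#' Fisher z-transformed (atanh); diagonal set to 0. Zero-variance rows give
#' missing entries with a warning.
#'
#' @param tc N x T matrix of ROI time courses.
#' @param scan_id,subject_id identifiers carried along.
#' @return an object of class `fc_matrix`: `z` (N x N), `roi_ids`,
#'   `scan_id`, `subject_id`.
#' @export
scan_fc <- function(tc, scan_id = NA_character_,
                    subject_id = NA_character_) {
  if (ncol(tc) < 3L) stop("need at least 3 time points")
  sds <- apply(tc, 1, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate))
    warning("zero-variance ROI time course(s): ",
            paste(rownames(tc)[degenerate], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(tc)))
  r[degenerate, ] <- NA; r[, degenerate] <- NA
  cap <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -cap), cap))
  diag(z) <- 0
  roi_ids <- rownames(tc)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(nrow(tc)))
  structure(list(z = z, roi_ids = roi_ids, scan_id = scan_id,
                 subject_id = subject_id),
            class = "fc_matrix")
}

# Upper-triangle index pairs of an N x N matrix, and vector extraction.
upper_tri_vec <- function(m) m[upper.tri(m)]

vec_to_sym <- function(v, n, diag_value = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}
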