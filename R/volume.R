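#' 4D BOLD volume
#'
#' The universal carrier between pipeline stages: a 4D voxel array
#' (x, y, z, t) with its voxel size in mm, repetition time in seconds and a
#' 4x4 voxel-to-world affine. A 3D array is promoted to a single-frame 4D
#' volume.
#'
#' @param data numeric 3D or 4D array.
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param tr_s positive scalar, repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). Default:
#'   scaling by `voxel_size_mm` with the world origin at the grid centre.
#' @return an object of class `volume4d` with fields `data`, `voxel_size_mm`,
#'   `tr_s`, `affine`.
#' @export
volume4d <- function(data, voxel_size_mm = c(1, 1, 1), tr_s = 1,
                     affine = NULL) {
  if (!is.array(data)) stop("`data` must be a 3D or 4D array")
  d <- dim(data)
  if (length(d) == 3L) {
    dim(data) <- c(d, 1L)
    d <- dim(data)
  }
  if (length(d) != 4L) stop("`data` must be a 3D or 4D array")
  if (any(d < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume data contains non-finite values")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers")
  tr_s <- as.numeric(tr_s)
  if (length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a positive scalar")
  if (is.null(affine)) affine <- default_affine(voxel_size_mm, d[1:3])
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 affine = affine),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d x %d, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size_mm, 3), collapse = " x "), x$tr_s))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

#' Number of frames of a volume
#' @param vol a `volume4d`.
#' @return integer frame count.
#' @export
n_frames <- function(vol) dim(vol$data)[4]

default_affine <- function(voxel_size_mm, dim3) {
  a <- diag(c(voxel_size_mm, 1))
  a[1:3, 4] <- -voxel_size_mm * (dim3 - 1) / 2
  a
}

#' Extract one 3D frame from a 4D volume
#' @param vol a `volume4d`.
#' @param t frame index (1-based).
#' @return numeric 3D array.
#' @export
get_frame <- function(vol, t) {
  d <- dim(vol$data)
  if (t < 1 || t > d[4]) stop("frame index out of range")
  array(vol$data[, , , t], dim = d[1:3])
}

# Frames x voxels matrix of the in-mask time courses.
vol_to_matrix <- function(vol, mask = NULL) {
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  t(m)
}

# Inverse of vol_to_matrix: write a T x V matrix back into vol's grid.
matrix_to_vol <- function(mat, vol, mask = NULL, fill = 0) {
  d <- dim(vol$data)
  nt <- nrow(mat)
  out <- matrix(fill, nrow = prod(d[1:3]), ncol = nt)
  if (is.null(mask)) {
    stopifnot(ncol(mat) == prod(d[1:3]))
    out[, ] <- t(mat)
  } else {
    out[as.logical(mask), ] <- t(mat)
  }
  volume4d(array(out, dim = c(d[1:3], nt)), vol$voxel_size_mm, vol$tr_s,
           vol$affine)
}

#' Tissue mask set
#'
#' Brain, white-matter and CSF masks on a common grid, plus a dilated brain
#' mask used to window motion correction. WM and CSF must be disjoint and
#' contained in the brain mask.
#'
#' @param brain,wm,csf logical 3D arrays on the same grid.
#' @param dilate integer, number of 6-connected dilation passes used to build
#'   `dilated_brain` when it is not supplied.
#' @param dilated_brain optional logical 3D array superset of `brain`.
#' @return an object of class `mask_set`.
#' @export
mask_set <- function(brain, wm, csf, dilate = 2L, dilated_brain = NULL) {
  d <- dim(brain)
  if (length(d) != 3L) stop("masks must be 3D")
  for (m in list(wm, csf)) {
    if (!identical(dim(m), d)) stop("all masks must share the same grid")
  }
  brain <- array(as.logical(brain), d)
  wm <- array(as.logical(wm), d)
  csf <- array(as.logical(csf), d)
  if (any(wm & csf)) stop("WM and CSF masks overlap")
  if (any((wm | csf) & !brain)) stop("WM/CSF masks extend outside the brain")
  if (is.null(dilated_brain)) {
    dilated_brain <- array(dilate3d_cpp(brain, d, as.integer(dilate)), d)
  } else {
    dilated_brain <- array(as.logical(dilated_brain), d)
    if (any(brain & !dilated_brain))
      stop("`dilated_brain` must contain the brain mask")
  }
  structure(list(brain = brain, wm = wm, csf = csf,
                 dilated_brain = dilated_brain),
            class = "mask_set")
}

#' Grey-matter mask of a mask set
#' @param masks a `mask_set`.
#' @return logical 3D array: brain voxels outside WM and CSF.
#' @export
gm_mask <- function(masks) masks$brain & !masks$wm & !masks$csf

#' Brain-boundary (edge) shell of a mask set
#' @param masks a `mask_set`.
#' @param width erosion depth in voxels defining the shell.
#' @return logical 3D array.
#' @export
edge_mask <- function(masks, width = 1L) {
  d <- dim(masks$brain)
  inner <- array(erode3d_cpp(masks$brain, d, as.integer(width)), d)
  masks$brain & !inner
}

#' Labeled ROI atlas
#'
#' An integer parcellation volume (0 = background) with per-label names,
#' brain-system assignments, and world-space centroids.
#'
#' @param labels integer 3D array, 0 for background.
#' @param names character vector named by label, or a data.frame with columns
#'   `label`, `name` and optionally `system`.
#' @param systems optional character vector named by label.
#' @param affine 4x4 voxel-to-world affine of the label grid.
#' @return an object of class `roi_atlas` with fields `labels`, `table`
#'   (data.frame: label, name, system, x/y/z centroid in mm).
#' @export
roi_atlas <- function(labels, names, systems = NULL, affine = NULL) {
  d <- dim(labels)
  if (length(d) != 3L) stop("`labels` must be a 3D array")
  labels <- array(as.integer(labels), d)
  if (is.data.frame(names)) {
    tab <- names
    if (is.null(tab$system)) tab$system <- "unassigned"
  } else {
    tab <- data.frame(label = as.integer(base::names(names)),
                      name = as.character(names),
                      stringsAsFactors = FALSE)
    tab$system <- if (is.null(systems)) "unassigned"
                  else as.character(systems[as.character(tab$label)])
  }
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, tab$label)
  if (length(missing))
    stop("labels without names: ", paste(missing, collapse = ", "))
  tab <- tab[tab$label %in% present, , drop = FALSE]
  tab <- tab[order(tab$label), , drop = FALSE]
  if (is.null(affine)) affine <- default_affine(c(1, 1, 1), d)
  cen <- t(vapply(tab$label, function(l) {
    idx <- which(labels == l, arr.ind = TRUE) - 1  # 0-based voxel coords
    v <- colMeans(idx)
    (affine %*% c(v, 1))[1:3]
  }, numeric(3)))
  tab$x_mm <- cen[, 1]; tab$y_mm <- cen[, 2]; tab$z_mm <- cen[, 3]
  rownames(tab) <- NULL
  structure(list(labels = labels, table = tab, affine = affine),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %d ROIs on a %s grid\n", nrow(x$table),
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Pairwise Euclidean distances between ROI centroids
#' @param atlas a `roi_atlas`.
#' @return N x N symmetric matrix of distances in mm.
#' @export
roi_distances <- function(atlas) {
  cen <- as.matrix(atlas$table[, c("x_mm", "y_mm", "z_mm")])
  d <- as.matrix(stats::dist(cen))
  dimnames(d) <- list(atlas$table$name, atlas$table$name)
  d
}

stopifnot_same_grid <- function(a_dim, b_dim, what) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(what, " is not on the data grid (", paste(a_dim, collapse = "x"),
         " vs ", paste(b_dim, collapse = "x"), "); no implicit resampling")
}
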