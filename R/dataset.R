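# Dataset layout: BIDS-like.
#   root/sub-XX/func/sub-XX_..._bold.nii[.gz]  (+ matching .json sidecar)
#   root/sub-XX/anat/...                       (optional)
#   root/derivatives/<pipeline>/sub-XX/...     (mirrored by the pipeline)

nifti_header_dim <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("truncated NIfTI header: ", path)
  endian <- "little"
  if (readBin(raw_hdr[1:4], "integer", 1L, 4L, endian = endian) != 348L)
    endian <- "big"
  dim_raw <- readBin(raw_hdr[41:56], "integer", 8L, 2L, endian = endian)
  ndim <- dim_raw[1]
  d <- dim_raw[2:(1 + max(ndim, 3L))]
  if (ndim < 4L) d <- c(d[1:3], 1L)
  d[1:4]
}

scan_record <- function(scan_id, subject_id, n_volumes, path_raw,
                        sidecar = list()) {
  if (length(sidecar$fd_mm) && length(sidecar$fd_mm) != n_volumes)
    stop(sprintf("scan %s: sidecar FD length %d != n_volumes %d",
                 scan_id, length(sidecar$fd_mm), n_volumes))
  structure(list(scan_id = scan_id, subject_id = subject_id,
                 n_volumes = as.integer(n_volumes), path_raw = path_raw,
                 sidecar = sidecar),
            class = "scan_record")
}

sidecar_path <- function(nii_path) {
  sub("\\.nii(\\.gz)?$", ".json", nii_path)
}

#' Discover functional scans in a dataset
#'
#' Walks a BIDS-like tree (`sub-*/func/*_bold.nii[.gz]`) and returns one
#' record per functional scan, in deterministic lexicographic order, paired
#' with its subject and JSON sidecar when present. Scans whose image cannot
#' be parsed are skipped with a warning.
#'
#' @param root dataset root directory.
#' @return list of `scan_record` objects (scan_id, subject_id, n_volumes,
#'   path_raw, sidecar).
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  subs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  subs <- subs[grepl("^sub-", basename(subs))]
  records <- list()
  for (s in subs) {
    subject_id <- basename(s)
    niis <- sort(list.files(file.path(s, "func"),
                            pattern = "_bold\\.nii(\\.gz)?$",
                            full.names = TRUE))
    for (p in niis) {
      d <- tryCatch(nifti_header_dim(p), error = function(e) NULL)
      if (is.null(d)) {
        warning("skipping unreadable scan image: ", p)
        next
      }
      sc <- list()
      jp <- sidecar_path(p)
      if (file.exists(jp))
        sc <- jsonlite::read_json(jp, simplifyVector = TRUE)
      scan_id <- sub("\\.nii(\\.gz)?$", "", basename(p))
      records[[length(records) + 1L]] <-
        scan_record(scan_id, subject_id, d[4], p, sc)
    }
  }
  records
}

#' Write a scan's JSON sidecar
#'
#' Stores the framewise-displacement series, scrub decisions and QC metrics
#' alongside the scan image, as the database convention requires.
#'
#' @param record a `scan_record` (or a list with `path_raw` and `n_volumes`).
#' @param fd numeric FD series, one value per acquired volume.
#' @param qc named list of additional QC fields (must be JSON-serializable).
#' @param path optional explicit sidecar path; defaults to the image path
#'   with a .json extension.
#' @return invisibly, the sidecar path.
#' @export
write_sidecar <- function(record, fd, qc = list(), path = NULL) {
  fd <- as.numeric(fd)
  if (length(fd) != record$n_volumes)
    stop(sprintf("FD length %d != n_volumes %d for scan %s",
                 length(fd), record$n_volumes, record$scan_id))
  if (any(!is.finite(fd))) stop("FD series contains non-finite values")
  payload <- c(list(scan_id = record$scan_id, subject_id = record$subject_id,
                    n_volumes = record$n_volumes, fd_mm = fd,
                    mean_fd_mm = mean(fd)),
               qc)
  ok <- vapply(payload, function(x)
    is.numeric(x) || is.character(x) || is.logical(x) || is.list(x) ||
      is.null(x), logical(1))
  if (!all(ok))
    stop("non-serializable sidecar values: ",
         paste(names(payload)[!ok], collapse = ", "))
  if (is.null(path)) path <- sidecar_path(record$path_raw)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scan's JSON sidecar
#' @param record a `scan_record`, or a path to the image/sidecar.
#' @return named list, or empty list when no sidecar exists.
#' @export
read_sidecar <- function(record) {
  p <- if (is.character(record)) record else record$path_raw
  jp <- if (grepl("\\.json$", p)) p else sidecar_path(p)
  if (!file.exists(jp)) return(list())
  jsonlite::read_json(jp, simplifyVector = TRUE)
}
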