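# Characterization of the group FC matrix: distance dependence,
# structure-function agreement, reproducibility, and per-scan seed-FC
# specificity categories.

#' Correlation between FC and ROI distance
#'
#' Pearson correlation between the off-diagonal upper-triangle FC values
#' (group t or mean z) and the pairwise Euclidean distances between ROI
#' centroids.
#'
#' @param fc N x N symmetric FC matrix (group t or mean z).
#' @param distances N x N matrix of centroid distances in mm (e.g. from
#'   [roi_distances]).
#' @return list with `r`, `p`, `n_pairs`.
#' @export
fc_vs_distance <- function(fc, distances) {
  stopifnot(nrow(fc) >= 3L, all(dim(fc) == dim(distances)))
  x <- upper_tri_vec(distances)
  y <- upper_tri_vec(fc)
  if (stats::sd(x) == 0) stop("ROI distances have zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x))
}

#' Jaccard agreement between significant FC and structural connectivity
#'
#' Jaccard index of the two edge sets over the off-diagonal upper triangle,
#' with a permutation p-value from a density-matched Erdos-Renyi null
#' (random symmetric graphs with the FC edge count) or, optionally, a
#' degree-preserving rewiring null.
#'
#' @param sig_fc,sc logical/0-1 symmetric matrices on the same ROI set.
#' @param n_perm number of null graphs (default 1000).
#' @param seed integer seed.
#' @param null "density" (Erdos-Renyi at matched edge count) or "degree"
#'   (degree-preserving edge swaps).
#' @return list with `jaccard`, `p`, `n_edges_fc`, `n_edges_sc`.
#' @export
jaccard_fc_sc <- function(sig_fc, sc, n_perm = 1000L, seed = 1L,
                          null = c("density", "degree")) {
  null <- match.arg(null)
  stopifnot(all(dim(sig_fc) == dim(sc)))
  a <- upper_tri_vec(sig_fc != 0)
  b <- upper_tri_vec(sc != 0)
  uni <- sum(a | b)
  if (uni == 0) stop("both edge sets are empty")
  jac <- function(x, y) {
    u <- sum(x | y)
    if (u == 0) return(0)
    sum(x & y) / u
  }
  obs <- jac(a, b)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n_edge <- sum(a)
  m <- length(a)
  null_j <- vapply(seq_len(n_perm), function(i) {
    x <- if (null == "density") {
      v <- logical(m); v[sample.int(m, n_edge)] <- TRUE; v
    } else {
      rewire_degree_preserving(sig_fc != 0)
    }
    jac(x, b)
  }, numeric(1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  list(jaccard = obs, p = (1 + sum(null_j >= obs)) / (1 + n_perm),
       n_edges_fc = n_edge, n_edges_sc = sum(b))
}

# Degree-preserving double-edge swaps; returns the upper-tri vector.
rewire_degree_preserving <- function(adj, n_swaps = NULL) {
  n <- nrow(adj)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(edges)
  for (s in seq_len(n_swaps)) {
    if (nrow(edges) < 2L) break
    ij <- sample.int(nrow(edges), 2L)
    e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
    a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
    if (length(unique(c(a, b, c, d))) < 4L) next
    # propose (a,d) and (c,b)
    n1 <- sort(c(a, d)); n2 <- sort(c(c, b))
    if (adj[n1[1], n1[2]] || adj[n2[1], n2[2]]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[n1[1], n1[2]] <- adj[n1[2], n1[1]] <- TRUE
    adj[n2[1], n2[2]] <- adj[n2[2], n2[1]] <- TRUE
    edges[ij[1], ] <- n1
    edges[ij[2], ] <- n2
  }
  upper_tri_vec(adj)
}

regress_out_distance <- function(v, d) {
  stats::lm.fit(cbind(1, d), v)$residuals
}

#' Reproducibility of the group FC matrix
#'
#' Split-half: subjects are randomly divided into two subgroups, the mean-z
#' FC matrix of each is formed, ROI distance is regressed out of both
#' off-diagonal vectors, and their Pearson correlation is returned.
#' Leave-one-out: each subject's mean FC matrix is correlated (after the
#' same distance regression) with the group matrix excluding that subject.
#'
#' @param fc list of `fc_matrix` objects.
#' @param subjects character vector, subject of each scan.
#' @param mode "split_half" or "leave_one_out".
#' @param distances N x N ROI distance matrix, or NULL to skip the distance
#'   regression.
#' @param seed integer seed (split-half only).
#' @return for split-half: list with `r` and the two subgroup subject sets;
#'   for leave-one-out: list with `r_mean`, `r_sd` and per-subject `r`.
#' @export
reproducibility <- function(fc, subjects = NULL,
                            mode = c("split_half", "leave_one_out"),
                            distances = NULL, seed = 1L) {
  mode <- match.arg(mode)
  st <- stack_fc(fc, subjects)
  M <- subject_means(st$Z, st$subjects)
  ns <- ncol(M)
  dvec <- if (is.null(distances)) NULL else upper_tri_vec(distances)
  prep <- function(v) if (is.null(dvec)) v else regress_out_distance(v, dvec)
  if (mode == "split_half") {
    if (ns < 4L) stop("need at least 4 subjects for split-half")
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    half <- sample.int(ns, ns %/% 2L)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    g1 <- rowMeans(M[, half, drop = FALSE])
    g2 <- rowMeans(M[, -half, drop = FALSE])
    list(r = stats::cor(prep(g1), prep(g2)),
         subjects_a = colnames(M)[half], subjects_b = colnames(M)[-half])
  } else {
    if (ns < 3L) stop("need at least 3 subjects for leave-one-out")
    r <- vapply(seq_len(ns), function(i) {
      stats::cor(prep(M[, i]),
                 prep(rowMeans(M[, -i, drop = FALSE])))
    }, numeric(1))
    names(r) <- colnames(M)
    list(r_mean = mean(r), r_sd = stats::sd(r), r = r)
  }
}

#' Classify per-scan seed FC specificity
#'
#' Given a scan's Fisher-z FC between a seed and a specific reference ROI
#' (`z_specific`) and a non-specific reference ROI (`z_nonspecific`),
#' assigns one of four categories at threshold `thresh`: specific
#' (z_s > thresh >= z_n), unspecific (both above), none (both at or below),
#' spurious (z_s <= thresh < z_n).
#'
#' @param z_specific,z_nonspecific numeric vectors (one value per scan).
#' @param thresh Fisher-z threshold (default 0.1).
#' @return character vector of categories.
#' @export
specificity_classify <- function(z_specific, z_nonspecific, thresh = 0.1) {
  stopifnot(all(is.finite(z_specific)), all(is.finite(z_nonspecific)),
            length(z_specific) == length(z_nonspecific))
  s <- z_specific > thresh
  n <- z_nonspecific > thresh
  ifelse(s & !n, "specific",
         ifelse(s & n, "unspecific",
                ifelse(!s & !n, "none", "spurious")))
}

#' Specificity category tally for a set of scans
#'
#' Convenience wrapper computing, per scan, the seed-to-specific-ROI and
#' seed-to-nonspecific-ROI Fisher z from an FC matrix list, then tabulating
#' [specificity_classify] categories.
#'
#' @param fc list of `fc_matrix` objects.
#' @param seed_roi,specific_roi,nonspecific_roi ROI identifiers (matching
#'   `roi_ids`).
#' @param thresh Fisher-z threshold.
#' @return data.frame with one row per scan (`scan_id`, `z_specific`,
#'   `z_nonspecific`, `category`); attribute `tally` holds the fractions.
#' @export
specificity_table <- function(fc, seed_roi, specific_roi, nonspecific_roi,
                              thresh = 0.1) {
  get_z <- function(f, a, b) {
    ia <- match(as.character(a), f$roi_ids)
    ib <- match(as.character(b), f$roi_ids)
    if (is.na(ia) || is.na(ib)) stop("ROI not found in FC matrix")
    f$z[ia, ib]
  }
  zs <- vapply(fc, get_z, numeric(1), seed_roi, specific_roi)
  zn <- vapply(fc, get_z, numeric(1), seed_roi, nonspecific_roi)
  cat_ <- specificity_classify(zs, zn, thresh)
  out <- data.frame(scan_id = vapply(fc, function(f)
    as.character(f$scan_id), character(1)),
    z_specific = zs, z_nonspecific = zn, category = cat_,
    stringsAsFactors = FALSE)
  lv <- c("specific", "unspecific", "none", "spurious")
  attr(out, "tally") <- table(factor(cat_, levels = lv)) / nrow(out)
  out
}
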