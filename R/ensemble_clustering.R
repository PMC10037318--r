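# Daura-style greedy RMSD clustering of conformational ensembles.
#
# Conformations are plain natoms x 3 coordinate matrices (angstrom) over a
# fixed atom selection; an ensemble is a list of them. RMSD is computed
# after least-squares superposition (Kabsch, proper rotation enforced) by
# default, matching the behaviour of the reference gmx-cluster tool.

#' Extract a backbone ensemble from a trajectory
#'
#' @param traj A [trajectory()].
#' @param selection Atom names defining the backbone; N, CA, C by default
#'   (carbonyl O excluded, configurable).
#' @return List of `natoms x 3` matrices, one per frame, with attribute
#'   `atom_rows`.
#' @export
extract_backbone <- function(traj, selection = c("N", "CA", "C")) {
  rows <- which(!traj$atoms$is_slab & traj$atoms$name %in% selection)
  if (length(rows) < 3L)
    stop_input("backbone selection matched %d atoms; need >= 3", length(rows))
  ens <- lapply(seq_len(n_frames(traj)), function(i)
    matrix(traj$coords[rows, , i], ncol = 3L))
  attr(ens, "atom_rows") <- rows
  ens
}

# Optimal proper rotation (Kabsch via SVD) aligning b onto a after both are
# centred; reflection corrected through the determinant sign.
kabsch_rotation <- function(a, b) {
  h <- crossprod(b, a)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Backbone RMSD between two conformations
#'
#' Root-mean-squared deviation of atomic positions, optionally after
#' removing the centroids and applying the optimal (Kabsch) superposition.
#' Symmetric in its arguments and always >= 0.
#'
#' @param a,b `n x 3` coordinate matrices with equal atom counts (n >= 3).
#' @param fit Superpose before computing the deviation (default TRUE).
#' @return RMSD in the coordinate unit (angstrom).
#' @export
backbone_rmsd <- function(a, b, fit = TRUE) {
  if (nrow(a) != nrow(b))
    stop_input("atom-count mismatch: %d vs %d", nrow(a), nrow(b))
  if (nrow(a) < 3L) stop_input("need >= 3 atoms for RMSD")
  if (fit) {
    a <- sweep(a, 2L, colMeans(a))
    b <- sweep(b, 2L, colMeans(b))
    b <- b %*% kabsch_rotation(a, b)
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

#' All-pair RMSD matrix for an ensemble
#'
#' @param ensemble List of `n x 3` coordinate matrices.
#' @param fit Superpose each pair before the deviation.
#' @return Symmetric `n x n` matrix of RMSD values (angstrom).
#' @export
rmsd_matrix <- function(ensemble, fit = TRUE) {
  n <- length(ensemble)
  if (fit) ensemble <- lapply(ensemble, function(m) sweep(m, 2L, colMeans(m)))
  nat <- nrow(ensemble[[1]])
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    a <- ensemble[[i]]
    for (j in (i + 1L):n) {
      b <- ensemble[[j]]
      if (fit) b <- b %*% kabsch_rotation(a, b)
      d[i, j] <- d[j, i] <- sqrt(sum((a - b)^2) / nat)
    }
  }
  d
}

#' Greedy Daura clustering of a conformational ensemble
#'
#' Repeatedly counts, for every unassigned conformation, its neighbours
#' within the cut-off (inclusive, RMSD <= cutoff); the conformation with the
#' most neighbours becomes a cluster centroid and is removed together with
#' its neighbours; this repeats until no conformation remains. Ties on
#' neighbour count are broken by the lowest frame index. The centroid is the
#' max-neighbour member structure itself, not a coordinate average.
#'
#' @param ensemble List of `n x 3` coordinate matrices, or a precomputed
#'   symmetric distance matrix.
#' @param cutoff Neighbour cut-off in angstrom (> 0); the reference analysis
#'   used 2.0 angstrom on backbone atoms.
#' @param fit Superpose pairs before RMSD (ignored for a distance matrix).
#' @return A `cluster_result`: list of clusters (members, centroid frame
#'   index, population), ordered by decreasing population with ties by
#'   centroid index; plus the cut-off and, when built from an ensemble, the
#'   centroid coordinates for cross-matching.
#' @export
daura_cluster <- function(ensemble, cutoff = 2.0, fit = TRUE) {
  if (cutoff <= 0) stop_input("cutoff must be positive")
  from_matrix <- is.matrix(ensemble)
  if (!from_matrix && length(ensemble) == 0L)
    stop_input("empty ensemble")
  dmat <- if (from_matrix) ensemble else rmsd_matrix(ensemble, fit = fit)
  n <- nrow(dmat)
  if (n == 0L) stop_input("empty ensemble")
  adj <- dmat <= cutoff
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    idx <- which(alive)
    counts <- rowSums(adj[idx, idx, drop = FALSE])
    best <- idx[which.max(counts)]  # which.max takes the first = lowest index
    members <- idx[adj[best, idx]]
    clusters[[length(clusters) + 1L]] <-
      list(members = members, centroid = best, population = length(members))
    alive[members] <- FALSE
  }
  pops <- vapply(clusters, `[[`, 0, "population")
  cents <- vapply(clusters, `[[`, 0, "centroid")
  ord <- order(-pops, cents)
  clusters <- clusters[ord]
  out <- structure(list(clusters = clusters, cutoff = cutoff, n_frames = n),
                   class = "cluster_result")
  if (!from_matrix)
    out$centroid_coords <- lapply(clusters,
                                  function(cl) ensemble[[cl$centroid]])
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) over %d frames, cutoff %.2f A\n",
              length(x$clusters), x$n_frames, x$cutoff))
  print(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cluster_result <- function(x, ...) {
  data.frame(cluster = seq_along(x$clusters),
             centroid_frame = vapply(x$clusters, `[[`, 0, "centroid"),
             population = vapply(x$clusters, `[[`, 0, "population"))
}

#' Frame-to-cluster assignment vector
#' @param result A `cluster_result`.
#' @return Integer vector: cluster id (rank by population) per frame.
#' @export
cluster_assignments <- function(result) {
  out <- integer(result$n_frames)
  for (k in seq_along(result$clusters))
    out[result$clusters[[k]]$members] <- k
  out
}

#' Write cluster assignments as TSV
#' @param result A `cluster_result`.
#' @param path Output file.
#' @param header Extra `#`-prefixed header lines.
#' @export
write_cluster_assignments <- function(result, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pepsurf clusters; cutoff=%g A; n_clusters=%d",
                       result$cutoff, length(result$clusters)), header), con)
  utils::write.table(data.frame(frame = seq_len(result$n_frames),
                                cluster = cluster_assignments(result)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match clusters across two ensembles by centroid RMSD
#'
#' Compares every centroid pair among the `top_k` most populated clusters of
#' each result. A pair is `matched` when the centroid backbone RMSD is
#' <= `match_cutoff` (2.0 angstrom by default), `near-matched` when it lies
#' strictly between `match_cutoff` and `near_cutoff` (2.5 angstrom), and
#' `unmatched` otherwise.
#'
#' @param a,b `cluster_result` objects built from ensembles (they carry the
#'   centroid coordinates).
#' @param top_k Number of most-populated clusters of each result to compare;
#'   if a result has fewer, what exists is compared and a warning recorded.
#' @param match_cutoff,near_cutoff Status thresholds in angstrom.
#' @param fit Superpose centroid pairs before RMSD.
#' @return A `match_report` data frame: cluster ids, centroid RMSD, status;
#'   attribute `warnings` lists any truncation.
#' @export
cross_cluster_match <- function(a, b, top_k = 5L, match_cutoff = 2.0,
                                near_cutoff = 2.5, fit = TRUE) {
  if (top_k < 1L) stop_input("top_k must be >= 1")
  if (is.null(a$centroid_coords) || is.null(b$centroid_coords))
    stop_input("cluster results lack centroid coordinates; cluster from an ensemble")
  warnings <- character()
  ka <- min(top_k, length(a$clusters))
  kb <- min(top_k, length(b$clusters))
  if (ka < top_k || kb < top_k)
    warnings <- sprintf("fewer than top_k=%d clusters available (A: %d, B: %d)",
                        top_k, length(a$clusters), length(b$clusters))
  grid <- expand.grid(cluster_a = seq_len(ka), cluster_b = seq_len(kb))
  rmsd <- mapply(function(i, j)
    backbone_rmsd(a$centroid_coords[[i]], b$centroid_coords[[j]], fit = fit),
    grid$cluster_a, grid$cluster_b)
  status <- ifelse(rmsd <= match_cutoff, "matched",
                   ifelse(rmsd < near_cutoff, "near-matched", "unmatched"))
  out <- data.frame(grid, centroid_rmsd = rmsd, status = status)
  attr(out, "warnings") <- warnings
  attr(out, "thresholds") <- c(match = match_cutoff, near = near_cutoff)
  class(out) <- c("match_report", "data.frame")
  out
}

#' Write a cluster match report as TSV
#' @param report A `match_report`.
#' @param path Output file.
#' @export
write_match_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- attr(report, "thresholds")
  writeLines(sprintf("# pepsurf cluster match; matched <= %g A; near-matched < %g A",
                     th[["match"]], th[["near"]]), con)
  for (w in attr(report, "warnings")) writeLines(paste("# warning:", w), con)
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
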