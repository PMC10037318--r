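# Independent reference implementations and fixture builders used across the
# suite. These deliberately avoid the package's own code paths (plain loops,
# random search) so they can serve as oracles.

# Exhaustive, loop-based execution of the greedy max-neighbour clustering
# rule on a distance matrix. Ties on neighbour count broken by lowest index.
daura_reference <- function(dmat, cutoff) {
  n <- nrow(dmat)
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    best <- NA_integer_
    best_count <- -1L
    for (i in seq_len(n)) {
      if (!alive[i]) next
      cnt <- 0L
      for (j in seq_len(n)) if (alive[j] && dmat[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    members <- integer()
    for (j in seq_len(n)) if (alive[j] && dmat[best, j] <= cutoff)
      members <- c(members, j)
    clusters[[length(clusters) + 1L]] <- list(centroid = best,
                                              members = members,
                                              population = length(members))
    alive[members] <- FALSE
  }
  pops <- vapply(clusters, `[[`, 0, "population")
  cents <- vapply(clusters, `[[`, 0, "centroid")
  clusters[order(-pops, cents)]
}

# Symmetric random distance matrix with zero diagonal.
random_distance_matrix <- function(n, scale = 3) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0, scale)
  d + t(d)
}

# Minimum RMSD over rigid superpositions found by random rotation search
# plus translation removal; an independent check on the Kabsch solution.
rmsd_random_search <- function(a, b, n_rot = 20000L) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  best <- Inf
  for (i in seq_len(n_rot)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    r <- sqrt(sum((a - b %*% R)^2) / nrow(a))
    if (r < best) best <- r
  }
  best
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

# k well-separated template conformations: Gaussian chains rescaled until
# every fitted pairwise RMSD exceeds min_rmsd.
make_separated_templates <- function(k = 3L, n_atoms = 36L, seed = 42L,
                                     min_rmsd = 6) {
  set.seed(seed)
  scale <- 5
  repeat {
    tmpl <- lapply(seq_len(k), function(i)
      matrix(stats::rnorm(n_atoms * 3, sd = scale), n_atoms, 3))
    ok <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (backbone_rmsd(tmpl[[i]], tmpl[[j]]) <= min_rmsd) ok <- FALSE
    if (ok) return(tmpl)
    scale <- scale * 1.5
  }
}

# Small hand-built trajectory: a 3-layer 2x2 gold slab plus two single-atom
# residues at controllable heights above the top layer (z = 4.7 A).
make_toy_traj <- function(res_z, residue_names = c("CYS", "MET"),
                          site_names = c("SG", "SD")) {
  stopifnot(is.matrix(res_z), ncol(res_z) == length(residue_names))
  nf <- nrow(res_z)
  slab <- as.matrix(expand.grid(x = c(0, 2.88), y = c(0, 2.88),
                                z = c(0, 2.35, 4.7)))
  ns <- nrow(slab)
  nr <- length(residue_names)
  atoms <- data.frame(index = seq_len(ns + nr),
                      name = c(rep("AU", ns), site_names),
                      element = c(rep("Au", ns), rep("S", nr)),
                      residue_index = c(rep(0L, ns), seq_len(nr)),
                      residue_name = c(rep("AUS", ns), residue_names))
  coords <- array(0, c(ns + nr, 3, nf))
  for (i in seq_len(nf)) {
    coords[seq_len(ns), , i] <- slab
    coords[ns + seq_len(nr), 1, i] <- 1
    coords[ns + seq_len(nr), 2, i] <- 1
    coords[ns + seq_len(nr), 3, i] <- res_z[i, ]
  }
  trajectory(atoms, coords, c(5.76, 5.76, 40))
}
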