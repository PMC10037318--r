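test_that("RMSD is zero for identical structures and rigid motions, symmetric otherwise", {
  set.seed(21)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(backbone_rmsd(a, a), 0)
  # 90 degree rotation about z plus translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  b <- a %*% Rz + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  expect_lt(backbone_rmsd(a, b, fit = TRUE), 1e-6)
  expect_gt(backbone_rmsd(a, b, fit = FALSE), 1)
  d <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(backbone_rmsd(a, d), backbone_rmsd(d, a))
  expect_gte(backbone_rmsd(a, d), 0)
  expect_error(backbone_rmsd(a, a[1:5, ]), "mismatch")
})

test_that("Kabsch RMSD matches a brute-force rotation search on toy structures", {
  set.seed(33)
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 1.5, 1.5, 0, 0, 1.5, 1), 4, 3,
              byrow = TRUE)
  b <- a + matrix(c(0.3, -0.2, 0.4, 0, 0.1, -0.3, 0.2, 0.2, 0, -0.1, 0, 0.25),
                  4, 3, byrow = TRUE)
  kab <- backbone_rmsd(a, b, fit = TRUE)
  brute <- rmsd_random_search(a, b, n_rot = 30000L)
  expect_lte(kab, brute + 1e-9)       # Kabsch is the true minimum
  expect_equal(kab, brute, tolerance = 0.02)
})

test_that("degenerate clustering cases behave as defined", {
  a <- matrix(rnorm(30), 10, 3)
  ens <- replicate(6, a, simplify = FALSE)
  res <- daura_cluster(ens, cutoff = 2)
  expect_length(res$clusters, 1L)
  expect_equal(res$clusters[[1]]$centroid, 1L)
  expect_equal(res$clusters[[1]]$population, 6L)

  # cutoff below the minimum pairwise distance -> all singletons, index order
  set.seed(2)
  d <- random_distance_matrix(5, scale = 4) + 1
  diag(d) <- 0
  res2 <- daura_cluster(d, cutoff = 0.5)
  expect_length(res2$clusters, 5L)
  expect_equal(vapply(res2$clusters, `[[`, 0, "centroid"), 1:5)
  expect_error(daura_cluster(list(), 2), "empty")
  expect_error(daura_cluster(ens, cutoff = 0), "positive")
})

test_that("greedy clustering matches the exhaustive reference on random matrices", {
  set.seed(7)
  for (trial in 1:30) {
    n <- sample(4:10, 1)
    d <- random_distance_matrix(n)
    cutoff <- runif(1, 0.5, 2.5)
    got <- daura_cluster(d, cutoff)
    ref <- daura_reference(d, cutoff)
    expect_length(got$clusters, length(ref))
    for (k in seq_along(ref)) {
      expect_identical(got$clusters[[k]]$centroid, ref[[k]]$centroid)
      expect_identical(sort(got$clusters[[k]]$members), sort(ref[[k]]$members))
    }
  }
})

test_that("clusters partition the frames and conserve population", {
  tmpl <- make_separated_templates(3, n_atoms = 24, seed = 5)
  sim <- gen_cluster_ensemble(tmpl, noise_rms = 0.4, n = 60, seed = 6)
  res <- daura_cluster(sim$ensemble, cutoff = 2)
  assign <- cluster_assignments(res)
  expect_true(all(assign >= 1))
  expect_equal(sum(vapply(res$clusters, `[[`, 0, "population")), 60)
  all_members <- sort(unlist(lapply(res$clusters, `[[`, "members")))
  expect_identical(all_members, 1:60)
  pops <- vapply(res$clusters, `[[`, 0, "population")
  expect_true(all(diff(pops) <= 0))  # ordered by decreasing population
})

test_that("relabelling frames permutes clusters consistently", {
  tmpl <- make_separated_templates(2, n_atoms = 18, seed = 8)
  sim <- gen_cluster_ensemble(tmpl, noise_rms = 0.3, n = 30, seed = 9)
  res <- daura_cluster(sim$ensemble, cutoff = 2)
  perm <- rev(seq_along(sim$ensemble))
  res_p <- daura_cluster(sim$ensemble[perm], cutoff = 2)
  # same cluster sizes; members map through the permutation
  expect_equal(sort(vapply(res$clusters, `[[`, 0, "population")),
               sort(vapply(res_p$clusters, `[[`, 0, "population")))
  sets <- lapply(res$clusters, function(cl) sort(cl$members))
  sets_p <- lapply(res_p$clusters, function(cl) sort(perm[cl$members]))
  for (s in sets_p) expect_true(any(vapply(sets, identical, TRUE, s)))
})

test_that("cross-cluster matching bands statuses by centroid RMSD", {
  tmpl <- make_separated_templates(3, n_atoms = 24, seed = 10)
  sim <- gen_cluster_ensemble(tmpl, noise_rms = 0.2, n = 45, seed = 11)
  res <- daura_cluster(sim$ensemble, cutoff = 2)

  # compared with itself: every diagonal pair matched at RMSD ~ 0
  self <- cross_cluster_match(res, res, top_k = 3)
  diag_rows <- self[self$cluster_a == self$cluster_b, ]
  expect_true(all(diag_rows$status == "matched"))
  expect_true(all(diag_rows$centroid_rmsd < 1e-8))

  # planted centroid displacements: 2.2 A -> near-matched, 3.0 A -> unmatched
  base <- matrix(rnorm(24 * 3, sd = 4), 24, 3)
  shift_by <- function(r) {
    out <- base
    out[, 1] <- out[, 1] + seq(-1, 1, length.out = 24) * 0  # keep shape
    # displace alternating atoms along x so the fitted RMSD hits ~r
    d <- rep(c(1, -1), length.out = 24)
    f <- stats::uniroot(function(s) backbone_rmsd(base, base + s * cbind(d, 0, 0)) - r,
                        c(0, 10))$root
    base + f * cbind(d, 0, 0)
  }
  ra <- daura_cluster(list(base, base), cutoff = 2)
  rb <- daura_cluster(list(shift_by(2.2), shift_by(2.2)), cutoff = 2)
  rc <- daura_cluster(list(shift_by(3.0), shift_by(3.0)), cutoff = 2)
  expect_identical(cross_cluster_match(ra, rb, top_k = 1)$status, "near-matched")
  expect_identical(cross_cluster_match(ra, rc, top_k = 1)$status, "unmatched")

  # fewer clusters than top_k: compare what exists, warn in the report
  few <- cross_cluster_match(ra, res, top_k = 5)
  expect_true(length(attr(few, "warnings")) > 0)
  expect_equal(nrow(few), 1 * min(5, length(res$clusters)))
})

test_that("backbone extraction picks N, CA, C and feeds clustering", {
  nat <- 4L
  atoms <- data.frame(index = 1:5,
                      name = c("N", "CA", "C", "O", "AU"),
                      element = c("N", "C", "C", "O", "Au"),
                      residue_index = c(1L, 1L, 1L, 1L, 0L),
                      residue_name = c("GLY", "GLY", "GLY", "GLY", "AUS"))
  coords <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  tr <- trajectory(atoms, coords, c(50, 50, 50))
  ens <- extract_backbone(tr)
  expect_length(ens, 2L)
  expect_equal(nrow(ens[[1]]), 3L)  # O and AU excluded
  expect_equal(attr(ens, "atom_rows"), 1:3)
})
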