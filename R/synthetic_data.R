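# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known ground truth, so all stages are testable without
# an MD run. All generators are pure functions of (spec, seed) and leave the
# caller's RNG state untouched.

#' Generate an adsorbed-peptide trajectory with prescribed contact statistics
#'
#' Per residue, a two-state first-order Markov chain with stationary contact
#' probability p_i and persistence rho decides contact/no-contact per frame;
#' in contact frames the residue's reference site sits `cutoff - 0.5`
#' angstrom above the topmost gold layer, otherwise `cutoff + 3` angstrom.
#' The slab is three Au(111)-like layers spaced 2.35 angstrom (a
#' representative interlayer distance; only placement relative to the
#' cut-off matters for contact tests). The ground-truth per-frame contact
#' matrix is returned alongside the trajectory.
#'
#' The persistence rho equals the lag-1 autocorrelation of the contact
#' indicator, modelling the temporal correlation of a real trajectory;
#' the effective sample size of a contact fraction estimated from n frames
#' is n (1 - rho) / (1 + rho).
#'
#' @param p Per-residue contact probabilities in `[0, 1]`.
#' @param n_frames Number of frames (>= 1).
#' @param rho Markov persistence in `[0, 1)`; default 0.5.
#' @param residue_names Residue type per position; default CYS (sulfur
#'   reference site) for all.
#' @param cutoffs Contact cut-off per residue (angstrom); default 4.5.
#' @param seed Integer seed; the same seed reproduces the trajectory
#'   bit-for-bit.
#' @param atoms_per_layer Slab atoms along each edge of a square layer.
#' @return List with `trajectory`, `contacts` (n_frames x n_residues logical
#'   ground truth) and the generating `spec`.
#' @export
gen_contact_trajectory <- function(p, n_frames, rho = 0.5,
                                   residue_names = rep("CYS", length(p)),
                                   cutoffs = rep(4.5, length(p)),
                                   seed = 1L, atoms_per_layer = 3L) {
  if (any(p < 0 | p > 1)) stop_input("contact probabilities must be in [0,1]")
  if (rho < 0 || rho >= 1) stop_input("persistence rho must be in [0,1)")
  if (n_frames < 1L) stop_input("need at least one frame")
  nr <- length(p)
  stopifnot(length(residue_names) == nr, length(cutoffs) == nr)

  # Au(111)-like slab: 3 square layers, 2.35 A apart, 2.88 A lattice pitch
  a0 <- 2.88; dlayer <- 2.35
  g <- expand.grid(x = (seq_len(atoms_per_layer) - 1L) * a0,
                   y = (seq_len(atoms_per_layer) - 1L) * a0,
                   z = (0:2) * dlayer)
  slab_xyz <- as.matrix(g)
  ns <- nrow(slab_xyz)
  top_z <- max(slab_xyz[, 3])

  contacts <- with_seed(seed, {
    m <- matrix(FALSE, n_frames, nr)
    u <- matrix(stats::runif(n_frames * nr), n_frames, nr)
    state <- u[1, ] < p
    m[1, ] <- state
    if (n_frames > 1L) {
      p11 <- p + rho * (1 - p)   # stay-in-contact probability
      p01 <- p * (1 - rho)       # enter-contact probability
      for (t in 2:n_frames) {
        state <- u[t, ] < ifelse(state, p11, p01)
        m[t, ] <- state
      }
    }
    m
  })

  # site atom per residue, spread in x above the slab
  site_name <- ifelse(residue_names == "MET" | residue_names == "MOX",
                      "SD", ifelse(residue_names %in% c("CYS", "CTB", "COX"),
                                   "SG", "CB"))
  res_x <- a0 * (seq_len(nr) - 1L) %% (atoms_per_layer * a0)
  z_contact <- top_z + cutoffs - 0.5
  z_free <- top_z + cutoffs + 3

  nat <- ns + nr
  coords <- array(0, c(nat, 3L, n_frames))
  coords[seq_len(ns), 1, ] <- slab_xyz[, 1]
  coords[seq_len(ns), 2, ] <- slab_xyz[, 2]
  coords[seq_len(ns), 3, ] <- slab_xyz[, 3]
  coords[ns + seq_len(nr), 1, ] <- res_x
  coords[ns + seq_len(nr), 2, ] <- a0
  zmat <- t(ifelse(t(contacts), z_contact, z_free))  # n_frames x nr
  coords[ns + seq_len(nr), 3, ] <- t(zmat)

  atoms <- data.frame(
    index = seq_len(nat),
    name = c(rep("AU", ns), site_name),
    element = c(rep("Au", ns), substr(site_name, 1L, 1L)),
    residue_index = c(rep(0L, ns), seq_len(nr)),
    residue_name = c(rep("AUS", ns), residue_names))
  box <- c(atoms_per_layer * a0, atoms_per_layer * a0,
           top_z + max(cutoffs) + 20)
  traj <- trajectory(atoms, coords, box)
  list(trajectory = traj, contacts = contacts,
       spec = list(p = p, rho = rho, n_frames = n_frames, seed = seed,
                   residue_names = residue_names, cutoffs = cutoffs))
}

#' Generate a conformational ensemble with planted clusters
#'
#' Each conformation is a template drawn by weight plus an isotropic
#' Gaussian perturbation whose per-atom root-mean-square displacement equals
#' `noise_rms`, optionally followed by a random rigid rotation and
#' translation (harmless when RMSD is computed with superposition). True
#' template labels are returned for parameter-recovery tests.
#'
#' @param templates List of `n x 3` template coordinate matrices.
#' @param weights Template probabilities (simplex; normalised if needed).
#' @param noise_rms Per-atom RMS displacement (angstrom, >= 0).
#' @param n Ensemble size.
#' @param seed Integer seed.
#' @param rigid Apply a random rigid rotation/translation per conformation.
#' @return List with `ensemble` (list of matrices) and `labels` (integer
#'   template index per conformation).
#' @export
gen_cluster_ensemble <- function(templates, weights = NULL, noise_rms = 0.3,
                                 n = 300L, seed = 1L, rigid = TRUE) {
  if (length(templates) == 0L) stop_input("need at least one template")
  if (noise_rms < 0) stop_input("noise_rms must be >= 0")
  k <- length(templates)
  weights <- weights %||% rep(1 / k, k)
  if (any(weights < 0)) stop_input("weights must be non-negative")
  weights <- weights / sum(weights)
  nat <- nrow(templates[[1]])
  sdc <- noise_rms / sqrt(3)  # per-coordinate sd giving per-atom RMS noise_rms
  with_seed(seed, {
    labels <- sample.int(k, n, replace = TRUE, prob = weights)
    ensemble <- lapply(labels, function(l) {
      m <- templates[[l]] + matrix(stats::rnorm(nat * 3L, sd = sdc), nat, 3L)
      if (rigid) {
        R <- random_rotation()
        m <- m %*% R + matrix(stats::runif(3, -10, 10), nat, 3L, byrow = TRUE)
      }
      m
    })
    list(ensemble = ensemble, labels = labels)
  })
}

# Uniform random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Free-energy profile functions for umbrella-sampling oracles
#'
#' Returns U(xi) in kJ/mol for one of three analytic forms: `flat` (0
#' everywhere), `harmonic` (`0.5 * kappa * (xi - c)^2`), or `double_well`
#' (`a * (xi^2 - b^2)^2`, minima at +-b separated by a barrier `a * b^4`).
#'
#' @param form One of "flat", "harmonic", "double_well".
#' @param params Named list of parameters: `kappa`, `c` for harmonic;
#'   `a`, `b` for double_well.
#' @return Vectorised function of the reaction coordinate (nm).
#' @export
pmf_function <- function(form = c("flat", "harmonic", "double_well"),
                         params = list()) {
  form <- match.arg(form)
  switch(form,
    flat = function(xi) rep(0, length(xi)),
    harmonic = {
      kappa <- params$kappa %||% 1000
      cc <- params$c %||% 0
      function(xi) 0.5 * kappa * (xi - cc)^2
    },
    double_well = {
      # Defaults give a ~2.7 kJ/mol barrier with wells at +-0.25 nm and a
      # maximum gradient of ~110 kJ/mol/nm over +-0.4 nm, gentle enough
      # that a 3000 kJ/mol/nm^2 harmonic bias (displacement |U'|/k <~ 0.04
      # nm) restrains every window near its centre.
      a <- params$a %||% 700
      b <- params$b %||% 0.25
      function(xi) a * (xi^2 - b^2)^2
    })
}

#' Draw exact Boltzmann samples for umbrella windows over a known PMF
#'
#' For each window j the biased density p_j(xi) is proportional to
#' exp(-(U(xi) + k/2 (xi - z0_j)^2) / kT); samples are drawn exactly from it
#' by inverse-CDF lookup on a dense grid (10^4 points by default). This is
#' the independent oracle for WHAM recovery tests: the true PMF is known.
#'
#' @param U Free-energy function of the reaction coordinate (kJ/mol vs nm),
#'   e.g. from [pmf_function()].
#' @param centers Window centres z0 (nm), all inside `range`.
#' @param k Bias force constant (kJ mol^-1 nm^-2); default 3000.
#' @param n_per_window Samples per window.
#' @param range `c(lo, hi)` support for the inverse-CDF grid (nm).
#' @param temperature Temperature in K.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param grid_n Grid resolution for the inverse CDF.
#' @return List of [umbrella_window()] objects.
#' @export
gen_umbrella_samples <- function(U, centers, k = 3000, n_per_window = 1000L,
                                 range = NULL, temperature = 300, seed = 1L,
                                 grid_n = 10000L) {
  if (is.null(range))
    range <- c(min(centers) - 0.15, max(centers) + 0.15)
  if (any(centers < range[1] | centers > range[2]))
    stop_input("all window centres must lie inside the range")
  kt <- kT(temperature)
  xi <- seq(range[1], range[2], length.out = grid_n)
  u_xi <- U(xi)
  with_seed(seed, {
    lapply(centers, function(z0) {
      loge <- -(u_xi + 0.5 * k * (xi - z0)^2) / kt
      loge <- loge - max(loge)
      w <- exp(loge)
      tot <- sum(w)
      if (!is.finite(tot) || tot <= 0)
        stop_input("unnormalizable biased density at z0=%.3f", z0)
      cdf <- cumsum(w) / tot
      # strictly increasing knots for interpolation
      keep <- c(TRUE, diff(cdf) > 0)
      s <- stats::approx(cdf[keep], xi[keep], stats::runif(n_per_window),
                         rule = 2)$y
      umbrella_window(z0, k, s)
    })
  })
}
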