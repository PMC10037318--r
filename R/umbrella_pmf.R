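# WHAM estimation of a 1-D potential of mean force from umbrella-sampling
# windows with harmonic biases, with trajectory-bootstrap error bars.
#
# Conventions follow common pull-code output: reaction coordinate in nm,
# force constants in kJ mol^-1 nm^-2, energies in kJ/mol. The WHAM
# self-consistency is iterated in log space for numerical stability.

#' Construct an umbrella window
#'
#' @param z0 Harmonic bias centre (nm).
#' @param k Force constant (kJ mol^-1 nm^-2); the reference protocol used
#'   3000 kJ mol^-1 nm^-2 with windows every 0.05 nm.
#' @param samples Reaction-coordinate samples (nm), in trajectory order.
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(z0, k, samples) {
  if (k <= 0) stop_input("force constant must be positive")
  if (length(samples) < 1L) stop_input("window needs at least one sample")
  if (!all(is.finite(samples))) stop_input("non-finite samples in window")
  structure(list(z0 = z0, k = k, samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' Read umbrella windows from a metadata file plus series files
#'
#' The metadata file is whitespace/tab-delimited with columns `file`,
#' `z0_nm`, `k_kJ_per_mol_nm2` (header required; `#` comments allowed).
#' Each series file is two-column whitespace-delimited time vs reaction
#' coordinate, the layout emitted by common MD engines' pull modules;
#' only the second column is used.
#'
#' @param metadata_path Path to the metadata file; series paths are resolved
#'   relative to its directory.
#' @return List of [umbrella_window()] objects.
#' @export
read_umbrella_windows <- function(metadata_path) {
  meta <- utils::read.table(metadata_path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
  need <- c("file", "z0_nm", "k_kJ_per_mol_nm2")
  if (!all(need %in% names(meta)))
    stop_input("umbrella metadata needs columns: %s", paste(need, collapse = ", "))
  dir <- dirname(metadata_path)
  lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, meta$file[i])
    ts <- utils::read.table(f, header = FALSE, comment.char = "#")
    umbrella_window(meta$z0_nm[i], meta$k_kJ_per_mol_nm2[i], ts[[2]])
  })
}

#' Write umbrella windows as a metadata file plus series files
#'
#' @param windows List of `umbrella_window` objects.
#' @param dir Output directory (created if absent).
#' @param dt Time step (ps) used to synthesise the time column.
#' @return Path to the metadata file.
#' @export
write_umbrella_windows <- function(windows, dir, dt = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.xvg", seq_along(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    utils::write.table(
      data.frame(time = dt * (seq_along(w$samples) - 1L), xi = w$samples),
      file.path(dir, files[i]), sep = " ", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  meta <- file.path(dir, "windows.meta")
  utils::write.table(
    data.frame(file = files,
               z0_nm = vapply(windows, `[[`, 0, "z0"),
               k_kJ_per_mol_nm2 = vapply(windows, `[[`, 0, "k")),
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  meta
}

#' Potential of mean force by the weighted histogram analysis method
#'
#' Solves the standard WHAM self-consistency for umbrella windows with
#' harmonic biases w_j(xi) = k/2 (xi - z0_j)^2: the unbiased bin probability
#' is p(xi_b) proportional to sum_j n_jb / sum_j N_j exp((F_j - w_j(xi_b))/kT),
#' with window free energies F_j = -kT log sum_b p(xi_b) exp(-w_j(xi_b)/kT),
#' iterated until the largest change in any F_j falls below the tolerance.
#' The PMF is -kT log p, gauge-fixed so its minimum over supported bins is
#' zero; bins with no counts are reported as NA, not 0.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param bins Number of histogram bins (>= 2); default 200.
#' @param range `c(lo, hi)` in nm; defaults to the sampled range.
#' @param temperature Temperature in K (default 300).
#' @param tolerance Convergence tolerance, by default relative to kT
#'   (`tol_mode = "kT"`, the gmx-wham-like convention); default 1e-6.
#' @param tol_mode "kT" (tolerance * kT in kJ/mol) or "absolute" (kJ/mol).
#' @param max_iter Iteration cap; exceeding it raises a convergence error.
#' @param f_init Initial window free energies F_j in kJ/mol (default all 0).
#'   The converged PMF is invariant to this choice — in particular to adding
#'   any constant — but a good guess (e.g. from a previous solution) cuts
#'   the iteration count, which the bootstrap exploits.
#' @return A `pmf_profile`: `grid` (bin centres, nm), `free_energy` (kJ/mol,
#'   NA at empty bins), `window_free_energies`, `counts`, `temperature`,
#'   `tolerance`, iteration count and first/final residuals.
#' @export
wham_pmf <- function(windows, bins = 200L, range = NULL, temperature = 300,
                     tolerance = 1e-6, tol_mode = c("kT", "absolute"),
                     max_iter = 100000L, f_init = NULL) {
  tol_mode <- match.arg(tol_mode)
  if (length(windows) < 1L) stop_input("need at least one umbrella window")
  if (bins < 2L) stop_input("need at least two bins")
  kt <- kT(temperature)
  if (is.null(range)) {
    allx <- unlist(lapply(windows, `[[`, "samples"))
    range <- stats::quantile(allx, c(0, 1), names = FALSE)
  }
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop_input("empty reaction-coordinate range")
  edges <- seq(lo, hi, length.out = bins + 1L)
  grid <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  J <- length(windows)
  counts <- matrix(0, J, bins)
  for (j in seq_len(J)) {
    x <- windows[[j]]$samples
    inside <- x >= lo & x <= hi
    if (!any(inside))
      stop_input("window %d (z0=%.3f) has no samples inside the range", j,
                 windows[[j]]$z0)
    b <- findInterval(x[inside], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts[j, ] <- tabulate(b, nbins = bins)
  }
  N <- rowSums(counts)
  # Log bias Boltzmann factors, J x bins. The factor is averaged over each
  # bin (5-point Gauss-Legendre) rather than evaluated at the centre: with
  # stiff biases the bias potential varies by ~kT across a bin and the
  # centre-point approximation leaves a visible systematic error.
  half <- (edges[2] - edges[1]) / 2
  gl_nodes <- c(-0.9061798459, -0.5384693101, 0, 0.5384693101, 0.9061798459)
  gl_w <- c(0.2369268851, 0.4786286705, 0.5688888889, 0.4786286705,
            0.2369268851) / 2
  logc <- t(vapply(windows, function(w) {
    vals <- vapply(seq_along(gl_nodes), function(q)
      gl_w[q] * exp(-0.5 * w$k * (grid + half * gl_nodes[q] - w$z0)^2 / kt),
      grid)
    log(rowSums(vals))
  }, grid))
  supp <- colSums(counts) > 0
  log_num <- log(colSums(counts))  # -Inf at empty bins, handled below
  f <- if (is.null(f_init)) numeric(J) else f_init / kt  # F_j / kT
  tol_f <- if (tol_mode == "kT") tolerance else tolerance / kt
  first_res <- NA_real_
  res <- Inf
  iter <- 0L
  logN <- log(N)
  while (iter < max_iter) {
    iter <- iter + 1L
    # log denominator per bin: logsumexp_j [ log N_j + f_j + logc_jb ]
    log_den <- col_logsumexp(logc + f + logN)
    logp <- log_num - log_den
    logp[!supp] <- -Inf
    # normalise p over supported bins (fixes the overall gauge each sweep)
    logp <- logp - logsumexp(logp[supp])
    f_new <- -row_logsumexp(sweep(logc[, supp, drop = FALSE], 2L, logp[supp],
                                  "+"))
    res <- max(abs(f_new - f))
    if (iter == 1L) first_res <- res
    f <- f_new
    if (res < tol_f) break
  }
  if (res >= tol_f)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                 max_iter, res), call. = FALSE)
  pmf <- -kt * logp
  pmf[!supp] <- NA_real_
  pmf <- pmf - min(pmf[supp])
  structure(list(grid = grid, free_energy = pmf,
                 errors = NULL,
                 window_free_energies = f * kt,
                 counts = counts, temperature = temperature,
                 tolerance = tolerance, tol_mode = tol_mode,
                 n_iter = iter, first_residual_kT = first_res,
                 final_residual_kT = res,
                 range = c(lo, hi), bins = bins),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  supp <- !is.na(x$free_energy)
  cat(sprintf("<pmf_profile> %d/%d supported bins over [%.3f, %.3f] nm; %d windows; %d iterations\n",
              sum(supp), length(x$grid), x$range[1], x$range[2],
              nrow(x$counts), x$n_iter))
  cat(sprintf("  PMF span %.3f kJ/mol at %d K%s\n",
              max(x$free_energy[supp]), x$temperature,
              if (!is.null(x$errors)) sprintf("; bootstrap errors attached (%d replicates)",
                                              attr(x$errors, "n_boot")) else ""))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$grid, x$free_energy, type = "l", xlab = "reaction coordinate (nm)",
       ylab = "PMF (kJ/mol)", ...)
  if (!is.null(x$errors)) {
    graphics::arrows(x$grid, x$free_energy - x$errors,
                     x$grid, x$free_energy + x$errors,
                     length = 0.02, angle = 90, code = 3, col = "grey60")
  }
  invisible(x)
}

# Integrated autocorrelation time of a series (initial positive sequence);
# used as the block length for the trajectory bootstrap. The lag window is
# capped at 1000: correlation times that long cannot be estimated reliably
# from the window lengths this analysis sees anyway.
estimate_block_length <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(1L)
  maxlag <- min(n - 1L, max(10L, n %/% 3L), 1000L)
  rho <- stats::acf(x, lag.max = maxlag, plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0.05)
  upto <- if (length(pos)) pos[1] - 1L else length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(upto)])
  max(1L, min(as.integer(round(tau)), n))
}

resample_blocks <- function(x, block) {
  n <- length(x)
  if (block >= n) return(x)
  nblk <- ceiling(n / block)
  starts <- sample.int(n - block + 1L, nblk, replace = TRUE)
  idx <- as.vector(outer(0:(block - 1L), starts, `+`))[seq_len(n)]
  x[idx]
}

#' Trajectory-bootstrap error bars for a WHAM PMF
#'
#' For each bootstrap replicate, every window's sample series is resampled
#' with replacement in contiguous blocks whose length equals the series'
#' integrated autocorrelation time estimate (minimum 1), WHAM is rerun, and
#' each replicate profile is gauge-aligned to the point estimate by its mean
#' offset over supported bins. The per-bin error is the standard deviation
#' across replicates. Deterministic for a given seed; the caller's RNG state
#' is untouched.
#'
#' @param windows List of [umbrella_window()] objects.
#' @param n_boot Number of replicates (>= 2); the reference protocol used
#'   200.
#' @param seed Integer seed.
#' @param block Block length: "auto" (per-window autocorrelation estimate),
#'   or an integer; block 0 forces a degenerate resampler that returns each
#'   series unchanged (useful to verify the zero-variance limit).
#' @param ... Passed to [wham_pmf()] (bins, range, temperature, tolerance...).
#' @return A `pmf_profile` (the point estimate) with `errors` filled in
#'   (kJ/mol per bin, NA at empty bins) and the replicate matrix in
#'   `attr(errors, "replicates")`.
#' @export
bootstrap_pmf_errors <- function(windows, n_boot = 200L, seed = 1L,
                                 block = "auto", ...) {
  if (n_boot < 2L) stop_input("n_boot must be >= 2")
  ref <- wham_pmf(windows, ...)
  supp <- !is.na(ref$free_energy)
  blocks <- if (identical(block, "auto"))
    vapply(windows, function(w) estimate_block_length(w$samples), 1L)
  else rep(as.integer(block), length(windows))
  reps <- with_seed(seed, {
    sapply(seq_len(n_boot), function(r) {
      ws <- lapply(seq_along(windows), function(j) {
        w <- windows[[j]]
        s <- if (blocks[j] <= 0L) w$samples
             else resample_blocks(w$samples, blocks[j])
        umbrella_window(w$z0, w$k, s)
      })
      prof <- wham_pmf(ws, bins = ref$bins, range = ref$range,
                       temperature = ref$temperature,
                       tolerance = ref$tolerance, tol_mode = ref$tol_mode,
                       f_init = ref$window_free_energies)
      fe <- prof$free_energy
      both <- supp & !is.na(fe)
      fe - mean(fe[both] - ref$free_energy[both])
    })
  })
  err <- apply(reps, 1L, stats::sd, na.rm = TRUE)
  err[!supp] <- NA_real_
  ref$errors <- err
  attr(ref$errors, "n_boot") <- n_boot
  attr(ref$errors, "replicates") <- reps
  ref
}

#' Write a PMF profile as TSV
#' @param profile A `pmf_profile`.
#' @param path Output file.
#' @param header Extra `#`-prefixed header lines.
#' @export
write_pmf_profile <- function(profile, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pepsurf PMF; T=%g K; tolerance=%g (%s); iterations=%d",
                       profile$temperature, profile$tolerance,
                       profile$tol_mode, profile$n_iter), header), con)
  df <- data.frame(xi_nm = profile$grid, pmf_kJ_per_mol = profile$free_energy)
  if (!is.null(profile$errors)) df$err_kJ_per_mol <- as.numeric(profile$errors)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
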