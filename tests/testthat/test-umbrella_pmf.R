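test_that("umbrella sampling oracle has the analytic Gaussian moments", {
  kt <- kT(300)
  # flat PMF, stiff bias: samples ~ N(z0, kT/k)
  k <- 3000
  win <- gen_umbrella_samples(pmf_function("flat"), centers = 0.3, k = k,
                              n_per_window = 20000, range = c(0.1, 0.5),
                              seed = 2)[[1]]
  se <- sqrt(kt / k / length(win$samples))
  expect_lt(abs(mean(win$samples) - 0.3), 3 * se)
  expect_equal(stats::var(win$samples), kt / k, tolerance = 0.05)

  # harmonic PMF kappa about c, bias k about z0: product of Gaussians
  kappa <- 2000; cc <- 0.2; z0 <- 0.3
  win2 <- gen_umbrella_samples(pmf_function("harmonic",
                                            list(kappa = kappa, c = cc)),
                               centers = z0, k = k, n_per_window = 20000,
                               range = c(0, 0.55), seed = 3)[[1]]
  mu <- (kappa * cc + k * z0) / (kappa + k)
  v <- kt / (kappa + k)
  expect_lt(abs(mean(win2$samples) - mu), 3 * sqrt(v / 20000))
  expect_equal(stats::var(win2$samples), v, tolerance = 0.05)
})

test_that("single near-unbiased window recovers a flat histogram PMF", {
  win <- gen_umbrella_samples(pmf_function("flat"), centers = 0.25, k = 1e-6,
                              n_per_window = 50000, range = c(0, 0.5),
                              seed = 4)
  prof <- wham_pmf(win, bins = 25, range = c(0, 0.5))
  supp <- !is.na(prof$free_energy)
  expect_true(all(supp))
  # flat within sampling noise (~kT/sqrt(2000 counts/bin) ~ 0.06 kJ/mol)
  expect_lt(max(prof$free_energy[supp]), 0.3)
  expect_equal(min(prof$free_energy[supp]), 0)   # gauge fixed at zero
})

test_that("WHAM is invariant to sample order and to the initial gauge", {
  centers <- seq(0.1, 0.4, by = 0.05)
  win <- gen_umbrella_samples(pmf_function("double_well"), centers, k = 3000,
                              n_per_window = 4000, range = c(0, 0.5), seed = 5)
  ref <- wham_pmf(win, bins = 60, range = c(0.1, 0.4))

  shuf <- lapply(win, function(w)
    umbrella_window(w$z0, w$k, rev(w$samples)))
  expect_equal(wham_pmf(shuf, bins = 60, range = c(0.1, 0.4))$free_energy,
               ref$free_energy)

  # adding a constant to all initial window free energies changes nothing
  off <- wham_pmf(win, bins = 60, range = c(0.1, 0.4),
                  f_init = rep(37, length(win)))
  expect_equal(off$free_energy, ref$free_energy, tolerance = 1e-6)
})

test_that("convergence diagnostics: residual drops and non-convergence errors", {
  centers <- seq(0.1, 0.4, by = 0.05)
  win <- gen_umbrella_samples(pmf_function("flat"), centers, k = 3000,
                              n_per_window = 2000, range = c(0, 0.5), seed = 6)
  prof <- wham_pmf(win, bins = 50, range = c(0.1, 0.4))
  expect_lt(prof$final_residual_kT, prof$first_residual_kT)
  expect_lt(prof$final_residual_kT, 1e-6)
  expect_error(wham_pmf(win, bins = 50, range = c(0.1, 0.4), max_iter = 3L),
               "converge")
  expect_error(wham_pmf(win, bins = 50, range = c(0.45, 0.5)),
               "no samples inside")
})

test_that("empty bins are reported as NA, not zero", {
  w1 <- umbrella_window(0.1, 3000, rep(c(0.09, 0.11), 200))
  w2 <- umbrella_window(0.4, 3000, rep(c(0.39, 0.41), 200))
  prof <- wham_pmf(list(w1, w2), bins = 50, range = c(0, 0.5))
  expect_true(anyNA(prof$free_energy))
  mid <- prof$grid > 0.2 & prof$grid < 0.3
  expect_true(all(is.na(prof$free_energy[mid])))
  supp <- !is.na(prof$free_energy)
  expect_equal(min(prof$free_energy[supp]), 0)
})

test_that("degenerate bootstrap resampling gives zero errors; seeds reproduce", {
  centers <- seq(0.15, 0.35, by = 0.05)
  win <- gen_umbrella_samples(pmf_function("flat"), centers, k = 3000,
                              n_per_window = 2000, range = c(0.05, 0.45),
                              seed = 7)
  bp0 <- bootstrap_pmf_errors(win, n_boot = 2, seed = 1, block = 0,
                              bins = 40, range = c(0.15, 0.35))
  expect_true(all(bp0$errors[!is.na(bp0$errors)] == 0))
  expect_error(bootstrap_pmf_errors(win, n_boot = 1), "n_boot")

  bp1 <- bootstrap_pmf_errors(win, n_boot = 5, seed = 42, bins = 40,
                              range = c(0.15, 0.35))
  bp2 <- bootstrap_pmf_errors(win, n_boot = 5, seed = 42, bins = 40,
                              range = c(0.15, 0.35))
  expect_identical(bp1$errors, bp2$errors)
  bp3 <- bootstrap_pmf_errors(win, n_boot = 5, seed = 43, bins = 40,
                              range = c(0.15, 0.35))
  expect_false(identical(as.numeric(bp1$errors), as.numeric(bp3$errors)))
})

test_that("bootstrap errors shrink roughly as 1/sqrt(samples per window)", {
  centers <- seq(0.15, 0.35, by = 0.05)
  err_at <- function(n) {
    win <- gen_umbrella_samples(pmf_function("flat"), centers, k = 3000,
                                n_per_window = n, range = c(0.05, 0.45),
                                seed = 8)
    bp <- bootstrap_pmf_errors(win, n_boot = 30, seed = 9, bins = 40,
                               range = c(0.15, 0.35))
    stats::median(bp$errors, na.rm = TRUE)
  }
  ratio <- err_at(8000) / err_at(2000)
  expect_lt(abs(ratio - 0.5), 0.15)
})

test_that("umbrella windows round-trip through the metadata + series layout", {
  win <- gen_umbrella_samples(pmf_function("flat"), centers = c(0.1, 0.15),
                              k = 3000, n_per_window = 50,
                              range = c(0, 0.3), seed = 10)
  dir <- withr::local_tempdir()
  meta <- write_umbrella_windows(win, dir)
  back <- read_umbrella_windows(meta)
  expect_length(back, 2L)
  expect_equal(back[[1]]$z0, 0.1)
  expect_equal(back[[2]]$k, 3000)
  expect_equal(back[[1]]$samples, win[[1]]$samples, tolerance = 1e-12)
})
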