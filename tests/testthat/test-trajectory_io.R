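test_that("units convert on load and round-trip through the text format", {
  sim <- gen_contact_trajectory(c(0.7, 0.3), n_frames = 3, seed = 7)
  traj <- sim$trajectory

  f <- withr::local_tempfile(fileext = ".txt")
  write_trajectory_txt(traj, f)
  back <- load_trajectory(f)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(back$box, traj$box, tolerance = 1e-3)
  expect_identical(back$atoms$residue_name, traj$atoms$residue_name)

  # the same file declared as nm comes back scaled by 10 (A -> nm -> A)
  nm <- load_trajectory(f, length_unit = "nanometer")
  expect_equal(nm$coords, traj$coords * 10, tolerance = 1e-2)
})

test_that("GRO frames are read as nm and converted to angstrom", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "toy peptide t= 2.0",
    "    3",
    "    1CYS    SG    1   0.100   0.200   1.000",
    "    2AUS    AU    2   0.000   0.000   0.000",
    "    2AUS    AU    3   0.288   0.000   0.000",
    "   5.80000   6.10000   6.80000"), f)
  traj <- load_trajectory(f)
  expect_equal(traj$coords[1, , 1], c(1, 2, 10))   # 1.00 nm z -> 10 A
  expect_equal(traj$box[1, ], c(58, 61, 68))
  expect_identical(traj$atoms$is_slab, c(FALSE, TRUE, TRUE))
  expect_equal(traj$time, 2)
})

test_that("PDB single- and multi-frame files load in angstrom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(i, nm, res, ri, x, y, z, el)
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm, res, ri, x, y, z, el)
  writeLines(c("CRYST1   57.600   57.600   68.000  90.00  90.00  90.00 P 1",
               "MODEL        1",
               atom_line(1, "AU", "AUS", 1, 0, 0, 0, "AU"),
               atom_line(2, "SG", "CYS", 2, 1, 1, 9.2, "S"),
               "ENDMDL",
               "MODEL        2",
               atom_line(1, "AU", "AUS", 1, 0, 0, 0, "AU"),
               atom_line(2, "SG", "CYS", 2, 1, 1, 5.0, "S"),
               "ENDMDL"), f)
  traj <- load_trajectory(f)
  expect_equal(n_frames(traj), 2L)
  expect_equal(traj$coords[2, 3, ], c(9.2, 5.0))
  expect_true(traj$atoms$is_slab[1])
})

test_that("atom-count mismatches name the offending file", {
  sim <- gen_contact_trajectory(c(0.5), n_frames = 2, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".txt")
  write_trajectory_txt(sim$trajectory, f1)
  sim2 <- gen_contact_trajectory(c(0.5, 0.5), n_frames = 1, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_trajectory_txt(sim2$trajectory, f2)
  expect_error(load_trajectory(f1, f2), "atom-count mismatch")
  expect_error(load_trajectory(f1, f2), basename(f2), fixed = TRUE)
})

test_that("loading is invariant to concatenation vs separate frame files", {
  sim <- gen_contact_trajectory(c(0.6, 0.4), n_frames = 4, seed = 3)
  whole <- withr::local_tempfile(fileext = ".txt")
  write_trajectory_txt(sim$trajectory, whole)
  lines <- readLines(whole)
  nat <- n_atoms(sim$trajectory)
  blocks <- split(lines, rep(seq_len(4), each = nat + 1L))
  parts <- vapply(seq_len(4), function(i) {
    p <- tempfile(fileext = ".txt")
    writeLines(blocks[[i]], p)
    p
  }, "")
  withr::defer(unlink(parts))
  a <- load_trajectory(whole)
  b <- load_trajectory(parts[1], parts[2:4])
  expect_equal(a$coords, b$coords)
  expect_equal(a$atoms, b$atoms)
})

test_that("partition covers every atom exactly once, in residue order", {
  sim <- gen_contact_trajectory(c(0.5, 0.5, 0.5), n_frames = 1, seed = 2)
  parts <- partition_atoms(sim$trajectory)
  pep_rows <- unlist(lapply(parts$peptide_residues, `[[`, "atom_rows"))
  all_rows <- sort(c(parts$slab_atoms, pep_rows))
  expect_identical(all_rows, seq_len(n_atoms(sim$trajectory)))
  expect_identical(vapply(parts$peptide_residues, `[[`, 0, "residue_index"),
                   c(1, 2, 3))

  # permutation invariance: shuffled atom order yields the same grouping
  traj <- sim$trajectory
  perm <- sample(n_atoms(traj))
  shuffled <- trajectory(traj$atoms[perm, ],
                         traj$coords[perm, , , drop = FALSE], traj$box)
  p2 <- partition_atoms(shuffled)
  expect_identical(length(p2$slab_atoms), length(parts$slab_atoms))
  for (g in seq_along(p2$peptide_residues)) {
    expect_identical(p2$peptide_residues[[g]]$residue_index,
                     parts$peptide_residues[[g]]$residue_index)
    expect_identical(sort(shuffled$atoms$index[p2$peptide_residues[[g]]$atom_rows]),
                     sort(traj$atoms$index[parts$peptide_residues[[g]]$atom_rows]))
  }
})

test_that("degenerate compositions are rejected with clear errors", {
  au <- data.frame(index = 1:2, name = "AU", element = "Au",
                   residue_index = c(0L, 0L), residue_name = "AUS")
  t_au <- trajectory(au, matrix(rnorm(6), 2, 3), c(10, 10, 10))
  expect_error(partition_atoms(t_au), "no peptide")

  pep <- data.frame(index = 1:2, name = "CA", element = "C",
                    residue_index = c(1L, 2L), residue_name = "GLY")
  t_pep <- trajectory(pep, matrix(rnorm(6), 2, 3), c(10, 10, 10))
  expect_error(partition_atoms(t_pep), "no slab")
})

test_that("explicit slab index lists override the element rule", {
  pep <- data.frame(index = 1:3, name = c("CA", "CA", "CA"), element = "C",
                    residue_index = 1:3, residue_name = "GLY")
  tr <- trajectory(pep, matrix(rnorm(9), 3, 3), c(10, 10, 10),
                   slab_indices = 1L)
  parts <- partition_atoms(tr)
  expect_identical(parts$slab_atoms, 1L)
  expect_length(parts$peptide_residues, 2L)
})
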