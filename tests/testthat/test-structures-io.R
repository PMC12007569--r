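# Structure containers, multi-model PDB round-trips, selection,
# superposition and buried surface area.

test_that("multi-model PDB round-trip preserves identity and coordinates", {
  withr::with_seed(11, {
    models <- lapply(1:3, function(i) {
      m <- random_atom_model(20, id = sprintf("m#%d", i))
      m$atoms$res_name <- "ALA"
      m
    })
  })
  path <- withr::local_tempfile(fileext = ".pdb")
  write_models(models, path)
  back <- read_models(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(nrow(back[[i]]$atoms), 20L)
    expect_identical(back[[i]]$atoms$res_seq, models[[i]]$atoms$res_seq)
    expect_identical(back[[i]]$atoms$atom_name, models[[i]]$atoms$atom_name)
    expect_lt(max(abs(coords(back[[i]]) - coords(models[[i]]))), 1e-3 + 1e-9)
  }
})

test_that("HETATM records and chain sets survive multi-model round-trips", {
  atoms <- rbind(
    atoms_df("A", 1:2, "CA", "C", c(0, 0, 0, 3, 0, 0), res_name = "ALA"),
    atoms_df("B", 10L, "C1", "C", c(5, 5, 5), res_name = "PYR", het = TRUE)
  )
  m1 <- structure_model("het#1", atoms)
  atoms2 <- atoms
  atoms2$x <- atoms2$x + 1
  m2 <- structure_model("het#2", atoms2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_models(list(m1, m2), path)
  back <- read_models(path)
  expect_length(back, 2L)
  for (b in back) {
    expect_setequal(unique(b$atoms$chain_id), c("A", "B"))
    expect_identical(b$atoms$het, c(FALSE, FALSE, TRUE))
    expect_identical(b$atoms$res_name[3L], "PYR")
  }
})

test_that("invalid atom records are hard read errors", {
  # duplicate (chain, res, atom) key within a model
  dup <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END")
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(dup, f1)
  expect_error(read_models(f1), "duplicate")
  # insertion code
  ins <- "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(ins, "END"), f2)
  expect_error(read_models(f2), "insertion")
  # unparsable coordinates, error names the line
  bad <- "ATOM      1  CA  ALA A   1       xxx.000   0.000   0.000  1.00  0.00          C"
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK", bad, "END"), f3)
  expect_error(read_models(f3), "line 2")
})

test_that("structure_model enforces its invariants", {
  expect_error(structure_model("x", atoms_df("A", c(1L, 1L), "CA", "C",
                                             c(0, 0, 0, 1, 1, 1))),
               "duplicate")
  bad <- atoms_df("A", 1L, "CA", "C", c(NA, 0, 0))
  expect_error(structure_model("x", bad), "non-finite")
  hyd <- structure_model("h", atoms_df("A", 1:2, c("CA", "H"), c("C", "H"),
                                       c(0, 0, 0, 1, 0, 0)))
  expect_identical(hyd$atoms$is_hydrogen, c(FALSE, TRUE))
})

test_that("select_atoms returns deterministic ordered heavy-atom sets", {
  atoms <- rbind(
    atoms_df("A", 2L, c("N", "CA", "HA"), c("N", "C", "H"),
             c(0, 0, 0, 1, 0, 0, 2, 0, 0), res_name = "ALA"),
    atoms_df("A", 1L, "CA", "C", c(3, 0, 0), res_name = "GLY")
  )
  m <- structure_model("sel#1", atoms)
  sel <- select_atoms(m, group_spec("A", 1:2))
  # ordered by residue number first, hydrogens excluded by default
  expect_identical(sel$res_seq, c(1L, 2L, 2L))
  expect_false(any(sel$is_hydrogen))
  sel_all <- select_atoms(m, group_spec("A", 1:2, heavy_only = FALSE))
  expect_gt(nrow(sel_all), nrow(sel))
  # a missing residue is an error naming the numbers, not an empty set
  expect_error(select_atoms(m, group_spec("A", c(1L, 7L, 9L))), "7, 9")
  expect_error(select_atoms(m, group_spec("C", 1L)), "missing residue")
})

test_that("superpose recovers exact and noisy rigid transforms", {
  withr::with_seed(7, ref <- matrix(runif(60, -5, 5), 20L, 3L))
  # identity
  s0 <- superpose(ref, ref)
  expect_lt(s0$rmsd, 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  # known transform: 30 degrees about z plus a translation
  R <- rot_matrix(c(0, 0, 1), 30)
  mob <- ref %*% t(R) + matrix(c(1, 2, 3), 20L, 3L, byrow = TRUE)
  s <- superpose(mob, ref)
  expect_lt(s$rmsd, 1e-10)
  expect_equal(s$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(mob, s) - ref)), 1e-9)
  # orthonormal, det +1
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("superposed rmsd of noisy copies matches the sqrt(3)*sigma law", {
  sigma <- 0.3
  n <- 100L
  rmsds <- withr::with_seed(13, vapply(1:50, function(i) {
    ref <- matrix(runif(3 * n, -8, 8), n, 3L)
    mob <- ref + matrix(rnorm(3 * n, 0, sigma), n, 3L)
    superpose(mob, ref)$rmsd
  }, numeric(1L)))
  expect_lt(abs(mean(rmsds) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.2)
})

test_that("superpose rejects degenerate or mismatched input", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "length")
  expect_error(superpose(matrix(1, 2, 3), matrix(1, 2, 3)), "3 paired atoms")
})

test_that("rmsd_unaligned is the plain paired RMSD", {
  withr::with_seed(5, a <- matrix(runif(30), 10L, 3L))
  expect_identical(rmsd_unaligned(a, a), 0)
  expect_equal(rmsd_unaligned(a, sweep(a, 2L, c(-3, 0, 0))), 3)
  b <- a + matrix(rnorm(30), 10L, 3L)
  # brute-force per-atom loop oracle
  direct <- sqrt(mean(vapply(1:10, function(i) sum((a[i, ] - b[i, ])^2),
                             numeric(1L))))
  expect_equal(rmsd_unaligned(a, b), direct, tolerance = 1e-12)
  # never below the superposed rmsd
  expect_gte(rmsd_unaligned(a, b) + 1e-12, superpose(a, b)$rmsd)
})

test_that("superpose is invariant to a common rigid transform", {
  withr::with_seed(21, {
    a <- matrix(runif(45, -5, 5), 15L, 3L)
    b <- a + matrix(rnorm(45, 0, 0.5), 15L, 3L)
  })
  base <- superpose(a, b)$rmsd
  R <- rot_matrix(c(1, 2, 2), 77)
  shift <- matrix(c(4, -2, 9), 15L, 3L, byrow = TRUE)
  moved <- superpose(a %*% t(R) + shift, b %*% t(R) + shift)$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("buried interface area matches geometry oracles", {
  # far-apart chains bury nothing
  far <- structure_model("far#1", rbind(
    atoms_df("A", 1L, "CA", "C", c(0, 0, 0)),
    atoms_df("B", 1L, "CA", "C", c(50, 0, 0))
  ))
  expect_equal(buried_interface_area(far, "A", "B"), 0)
  # tangent equal spheres: buried area equals the analytic spherical cap
  r_c <- 1.70
  probe <- 1.4
  touch <- structure_model("touch#1", rbind(
    atoms_df("A", 1L, "CA", "C", c(0, 0, 0)),
    atoms_df("B", 1L, "CA", "C", c(2 * r_c, 0, 0))
  ))
  R <- r_c + probe
  analytic <- 2 * pi * R * (R - r_c)  # cap height h = R - d/2
  got <- buried_interface_area(touch, "A", "B", probe = probe,
                               n_points = 960)
  expect_lt(abs(got - analytic) / analytic, 0.02)
  # lattice refinement changes the estimate by < 1%
  got2 <- buried_interface_area(touch, "A", "B", probe = probe,
                                n_points = 1920)
  expect_lt(abs(got2 - got) / got, 0.01)
  # symmetric in the two chains
  expect_equal(buried_interface_area(touch, "B", "A", n_points = 480),
               buried_interface_area(touch, "A", "B", n_points = 480),
               tolerance = 1e-9)
  expect_error(buried_interface_area(touch, "A", "C"), "no chain")
  unk <- structure_model("unk#1", rbind(
    atoms_df("A", 1L, "XX", "XX", c(0, 0, 0)),
    atoms_df("B", 1L, "CA", "C", c(3, 0, 0))
  ))
  expect_error(buried_interface_area(unk, "A", "B"), "van der Waals")
})
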