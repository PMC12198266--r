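test_that("kabsch returns identity on identical coordinate sets", {
  set.seed(59)
  A <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("kabsch recovers rigid motions exactly", {
  set.seed(61)
  A <- matrix(rnorm(45), 15, 3)
  for (i in 1:10) {
    R <- rot_xyz(runif(3, -pi, pi))
    tr <- rnorm(3, sd = 5)
    B <- A %*% t(R) + matrix(tr, 15, 3, byrow = TRUE)
    fit <- kabsch(A, B)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(fit$rotation, R, tolerance = 1e-9)
    # proper orthonormal rotation
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$rotation %*% t(fit$rotation), diag(3),
                 tolerance = 1e-9)
  }
})

test_that("rmsd is invariant under rigid motion and symmetric", {
  set.seed(67)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.4), 12, 3)
  base <- kabsch(A, B)$rmsd
  for (i in 1:5) {
    R <- rot_xyz(runif(3, -pi, pi))
    tr <- rnorm(3, sd = 3)
    A2 <- A %*% t(R) + matrix(tr, 12, 3, byrow = TRUE)
    expect_equal(kabsch(A2, B)$rmsd, base, tolerance = 1e-9)
  }
  expect_equal(kabsch(B, A)$rmsd, base, tolerance = 1e-9)
})

test_that("kabsch matches a brute-force rotational search on 4-point toys", {
  set.seed(71)
  for (i in 1:5) {
    A <- matrix(rnorm(12), 4, 3)
    B <- A %*% t(rot_xyz(runif(3, -pi, pi)))
    B[1, ] <- B[1, ] + rnorm(3, sd = 0.5)   # perturb one point
    got <- kabsch(A, B)$rmsd
    want <- oracle_min_rmsd(A, B)
    expect_equal(got, want, tolerance = 1e-3)
    expect_lte(got, want + 1e-6)            # optimality
    # independent reference implementation agrees (bio3d reports rmsd
    # rounded to 3 decimals)
    ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
    expect_lt(abs(got - ref), 5e-4)
  }
})

test_that("kabsch validates its input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 3, 3)), "equal-length")
  bad <- matrix(c(NA, rnorm(11)), 4, 3)
  expect_error(kabsch(bad, matrix(rnorm(12), 4, 3)), "finite")
})

test_that("read_calpha parses a hand-written PDB fixture in file order", {
  pdb <- tempfile(fileext = ".pdb")
  atom <- function(i, resname, resno, x, y, z, alt = " ", chain = "A")
    sprintf("ATOM  %5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, alt, resname, chain, resno, x, y, z)
  writeLines(c(atom(1, "MET", 1, 0, 0, 0),
               atom(2, "ALA", 2, 3.8, 0, 0),
               atom(3, "GLY", 3, 7.6, 0, 1),
               "END"), pdb)
  cc <- read_calpha(pdb)
  expect_s3_class(cc, "chain_coords")
  expect_equal(cc$one_letter_sequence, "MAG")
  expect_equal(cc$residue_numbers, 1:3)
  expect_equal(cc$calpha_xyz[, 1], c(0, 3.8, 7.6))

  # altloc: first location (A) taken
  writeLines(c(atom(1, "MET", 1, 0, 0, 0),
               atom(2, "ALA", 2, 3.8, 0, 0, alt = "A"),
               atom(3, "ALA", 2, 9.9, 0, 0, alt = "B"),
               atom(4, "GLY", 3, 7.6, 0, 1),
               "END"), pdb)
  cc2 <- read_calpha(pdb)
  expect_equal(nrow(cc2$calpha_xyz), 3)
  expect_equal(cc2$calpha_xyz[2, 1], 3.8)

  # chain selection: largest chain by default, named chain on request
  writeLines(c(atom(1, "MET", 1, 0, 0, 0, chain = "B"),
               atom(2, "ALA", 1, 0, 0, 0),
               atom(3, "GLY", 2, 3.8, 0, 0),
               atom(4, "CYS", 3, 7.6, 0, 0),
               "END"), pdb)
  expect_equal(read_calpha(pdb)$one_letter_sequence, "AGC")
  expect_equal(read_calpha(pdb, chain = "B")$one_letter_sequence, "M")

  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_calpha(empty), "cannot read")
})

test_that("superposition of a chain onto itself is exact", {
  set.seed(73)
  s <- rand_seq(80)
  a <- chain_coords("a", s, helix_coords(80))
  fit <- superpose_structures(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 80)
})

test_that("superposition handles deletions via sequence alignment", {
  set.seed(79)
  n <- 120
  s <- rand_seq(n)
  xyz <- helix_coords(n)
  keep <- setdiff(seq_len(n), 50:59)
  R <- rot_xyz(c(0.7, -0.3, 1.2))
  moved <- xyz[keep, ] %*% t(R) + matrix(c(1, -2, 3), length(keep), 3,
                                         byrow = TRUE)
  b <- chain_coords("b", paste(strsplit(s, "")[[1]][keep], collapse = ""),
                    moved)
  a <- chain_coords("a", s, xyz)
  fit <- superpose_structures(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$n_pairs, n - 10)
})

test_that("rejection iterations never increase the rmsd", {
  set.seed(83)
  n <- 100
  s <- rand_seq(n)
  xyz <- helix_coords(n)
  noisy <- xyz + matrix(rnorm(3 * n, sd = 0.3), n, 3)
  noisy[1:5, ] <- noisy[1:5, ] + 8       # a few gross outliers
  a <- chain_coords("a", s, xyz)
  b <- chain_coords("b", s, noisy)
  rmsds <- vapply(1:5, function(k)
    superpose_structures(a, b, max_iterations = k)$rmsd, numeric(1))
  expect_true(all(diff(rmsds) <= 1e-12))
  final <- superpose_structures(a, b)
  expect_lt(final$rmsd, rmsds[1])
  expect_lt(final$n_pairs, n)
})

test_that("superposition validates chain sizes", {
  a <- chain_coords("a", rand_seq(10), helix_coords(10))
  expect_error(superpose_structures(a, a), ">= 50")
})
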