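# Structure and trajectory I/O, selections, centers of mass.

pdb_line <- "ATOM      1  CA  ALA A   1      11.104  13.207   9.005  1.00 77.50           C"

test_that("a single ATOM record is parsed field-for-field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_line, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(unname(coords(m)[1, ]), c(11.104, 13.207, 9.005))
  expect_equal(m$atoms$bfactor, 77.50)
  expect_equal(m$atoms$chain_id, "A")
  expect_equal(m$atoms$element, "C")
  expect_false(m$atoms$is_hydrogen)
})

test_that("malformed records raise errors carrying the line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line, "ATOM      2  CB  ALA A   1      bad"), f)
  expect_error(read_structure(f), "line 2")
  writeLines(c("REMARK hello",
               sub("11.104", "x1.104", pdb_line, fixed = TRUE)), f)
  expect_error(read_structure(f), "line 2")
})

test_that("altloc policy keeps highest occupancy, ties won by letter A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C"
  ), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 2.0)  # higher occupancy wins

  writeLines(c(
    "ATOM      1  CA BALA A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50 10.00           C"
  ), f)
  m <- read_structure(f)
  expect_equal(m$atoms$x, 1.0)  # tie broken toward altloc A
})

test_that("multi-model files read as structure return frame 1 with warning", {
  cx <- make_complex(seed = 1, n_antigen = 6, n_heavy = 3, n_light = 3,
                     epitope = 2, low_nterm = 0)
  ens <- make_ensemble(cx$model, seed = 1, n_replicas = 1, n_frames = 3,
                       sigma = 0.2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(ens$ensemble$replicas[[1]], f)
  expect_warning(m <- read_structure(f), "first")
  expect_equal(coords(m),
               frame_coords(ens$ensemble$replicas[[1]], 1),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("trajectory frame times default to 0,1,2,... without remarks", {
  cx <- make_complex(seed = 1, n_antigen = 5, n_heavy = 2, n_light = 2,
                     epitope = 2, low_nterm = 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(0)
  for (i in 1:5) {
    m <- set_coords(cx$model, coords(cx$model) + i * 0.1)
    lines <- c(lines, sprintf("MODEL %5d", i),
               readLines(write_structure(m, withr::local_tempfile())),
               "ENDMDL")
  }
  writeLines(lines[lines != "END"], f)
  tr <- read_trajectory(f)
  expect_equal(tr$frame_times, 0:4)
  expect_equal(n_frames(tr), 5)
})

test_that("frames with inconsistent atom identity order are rejected", {
  a1 <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  a2 <- "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C"
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", a1, a2, "ENDMDL",
               "MODEL     2", a2, a1, "ENDMDL"), f)
  expect_error(read_trajectory(f), "inconsistent topology")
})

test_that("trajectory write/read round-trips coordinates, times, identity", {
  cx <- make_complex(seed = 3, n_antigen = 8, n_heavy = 4, n_light = 4,
                     epitope = c(2, 5), low_nterm = 0)
  ens <- make_ensemble(cx$model, seed = 5, n_replicas = 1, n_frames = 4,
                       sigma = 0.7, dt = 2.5)
  tr <- ens$ensemble$replicas[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$frame_times, tr$frame_times)
  expect_lt(max(abs(tr2$frames - tr$frames)), 1e-3 + 1e-9)
  expect_equal(tr2$topology$atoms$name, tr$topology$atoms$name)
  expect_equal(tr2$topology$atoms$chain_id, tr$topology$atoms$chain_id)
})

test_that("structure round-trip agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  cx <- make_complex(seed = 2, n_antigen = 10, n_heavy = 5, n_light = 5,
                     epitope = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx$model, f)
  ref <- bio3d::read.pdb(f)
  expect_lt(max(abs(matrix(ref$xyz, ncol = 3, byrow = TRUE) -
                    coords(cx$model))), 1e-3 + 1e-9)
  expect_equal(ref$atom$b, cx$model$atoms$bfactor, tolerance = 1e-2)
  expect_equal(ref$atom$chain, cx$model$atoms$chain_id)
})

test_that("selections resolve deterministically in file order", {
  m <- toy_model(data.frame(
    chain = c("A", "A", "A", "A", "A", "A", "B"),
    resid = c(1, 1, 1, 2, 2, 2, 1),
    name  = c("N", "CA", "H1", "N", "CA", "H1", "CA"),
    element = c("N", "C", "H", "N", "C", "H", "C"),
    x = 1:7, y = 0, z = 0))
  expect_equal(resolve_selection(m, "chain A and heavy"), c(1, 2, 4, 5))
  expect_equal(resolve_selection(m, "chain A and CA"), c(2, 5))
  expect_equal(resolve_selection(m, "chain B"), 7)
  expect_equal(resolve_selection(m, "resid 2 and heavy"), c(4, 5))
  expect_error(resolve_selection(m, "chain Z"), "unknown chain")
  # pure function: identical inputs, identical output
  expect_identical(resolve_selection(m, "chain A and heavy"),
                   resolve_selection(m, "chain A and heavy"))
  # empty result is allowed
  expect_length(resolve_selection(m, "chain B and hydrogen"), 0)
})

test_that("residue centers of mass are correct and translation-equivariant", {
  m <- toy_model(data.frame(
    chain = "A", resid = c(1, 2, 2, 3, 3, 3, 3),
    name = c("CA", "C1", "C2", "N", "CA", "C", "O"),
    element = c("C", "C", "C", "N", "C", "C", "O"),
    x = c(5, 0, 2, 0, 1, 2, 3), y = c(1, 0, 0, 0, 1, 0, 1),
    z = c(2, 0, 0, 1, 0, 0, 1)))
  xyz <- coords(m)
  # single atom: its own position
  expect_equal(residue_com(xyz, m, c("A", "1")), c(5, 1, 2))
  # two identical elements at (0,0,0) and (2,0,0): midpoint
  expect_equal(residue_com(xyz, m, c("A", "2")), c(1, 0, 0))
  # 4-atom residue, hand-computed mass-weighted mean
  mN <- 14.007; mC <- 12.011; mO <- 15.999
  w <- c(mN, mC, mC, mO)
  expect_equal(residue_com(xyz, m, c("A", "3")),
               as.numeric(colSums(xyz[4:7, ] * w) / sum(w)))
  # unweighted mean
  expect_equal(residue_com(xyz, m, c("A", "3"), mass_weighted = FALSE),
               colMeans(xyz[4:7, ]))
  # translation equivariance
  for (s in 1:5) {
    set.seed(s)
    t3 <- stats::rnorm(3, sd = 10)
    expect_equal(residue_com(sweep(xyz, 2, t3, "+"), m, c("A", "3")),
                 residue_com(xyz, m, c("A", "3")) + t3)
  }
  expect_error(residue_com(xyz, m, c("A", "9")), "not found")
})
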