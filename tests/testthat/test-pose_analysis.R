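# Rigid superposition, steric clash scanning, epitope mapping, competition.

test_that("superposing a set onto itself gives the identity transform", {
  set.seed(1)
  X <- matrix(stats::rnorm(30, sd = 8), 10, 3)
  tf <- kabsch_superpose(X, X)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(tf$fit_rmsd, 0, tolerance = 1e-10)
})

test_that("a known rigid motion is inverted exactly", {
  set.seed(2)
  X <- matrix(stats::rnorm(24, sd = 5), 8, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg z
  Y <- sweep(X %*% t(Rz), 2, c(3, -2, 7), "+")
  tf <- kabsch_superpose(Y, X)
  expect_lt(tf$fit_rmsd, 1e-6)
  expect_equal(apply_transform(Y, tf), X, tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the least-squares RMSD matches a numerical minimisation oracle", {
  X <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 4), 4, 3, byrow = TRUE)
  Y <- X
  Y[4, ] <- Y[4, ] + c(0.6, -0.4, 0.5)  # one perturbed point
  tf <- kabsch_superpose(Y, X)
  oracle <- numeric_superpose_rmsd(Y, X)
  expect_equal(tf$fit_rmsd, oracle, tolerance = 1e-3)
})

test_that("fit RMSD is invariant to rigid pre-transformation of mobile", {
  set.seed(3)
  X <- matrix(stats::rnorm(30, sd = 6), 10, 3)
  Y <- X + matrix(stats::rnorm(30, sd = 0.4), 10, 3)
  base <- kabsch_superpose(Y, X)$fit_rmsd
  for (s in 1:5) {
    set.seed(s)
    ang <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, byrow = TRUE)
    Y2 <- sweep(Y %*% t(R), 2, stats::rnorm(3, sd = 20), "+")
    expect_equal(kabsch_superpose(Y2, X)$fit_rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate fits are refused", {
  X <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  expect_error(kabsch_superpose(X, X), "collinear")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(X, X, fit_mobile = 1:3,
                                fit_reference = 1:2), "equal length")
})

test_that("clash detection uses a strict heavy-atom cutoff", {
  two <- function(d) {
    toy_model(data.frame(chain = c("A", "B"), resid = c(1, 1),
                         name = "CA", element = "C",
                         x = c(0, d), y = 0, z = 0))
  }
  r29 <- steric_clash_scan(two(2.9), "chain A", two(2.9), "chain B")
  expect_equal(nrow(r29$pairs), 1)
  expect_equal(r29$pairs$distance, 2.9)
  r31 <- steric_clash_scan(two(3.1), "chain A", two(3.1), "chain B")
  expect_equal(nrow(r31$pairs), 0)
  # hydrogens never clash
  hm <- toy_model(data.frame(chain = c("A", "B"), resid = c(1, 1),
                             name = c("CA", "H1"), element = c("C", "H"),
                             x = c(0, 1), y = 0, z = 0))
  expect_error(steric_clash_scan(hm, "chain A", hm, "chain B and hydrogen"),
               "empty")
})

test_that("clash pairs equal brute-force enumeration and are symmetric", {
  m <- random_cloud_model(30, seed = 7)
  rep_ab <- steric_clash_scan(m, "chain A", m, "chain B", cutoff = 3.0)
  ia <- resolve_selection(m, "chain A")
  ib <- resolve_selection(m, "chain B")
  oracle <- brute_pairs(coords(m)[ia, ], coords(m)[ib, ], 3.0)
  expect_equal(nrow(rep_ab$pairs), nrow(oracle))
  expect_equal(rep_ab$pairs$atom_a, ia[oracle$i])
  expect_equal(rep_ab$pairs$atom_b, ib[oracle$j])
  expect_equal(rep_ab$pairs$distance, oracle$distance, tolerance = 1e-12)
  # symmetry up to pair orientation
  rep_ba <- steric_clash_scan(m, "chain B", m, "chain A", cutoff = 3.0)
  key_ab <- paste(rep_ab$pairs$atom_a, rep_ab$pairs$atom_b)
  key_ba <- paste(rep_ba$pairs$atom_b, rep_ba$pairs$atom_a)
  expect_setequal(key_ab, key_ba)
})

test_that("epitope mapping reports contacting residues with pair counts", {
  cx <- make_complex(seed = 1, epitope = c(10, 11))
  ep <- epitope_map(cx$model, "chain A", "chain H L")
  expect_equal(ep$residue_key, c("10", "11"))
  expect_equal(ep$n_contacts, c(1, 1))
  # all distances beyond cutoff: empty map
  far <- epitope_map(cx$model, "chain A", "chain H L", cutoff = 1.0)
  expect_equal(nrow(far), 0)
  expect_error(epitope_map(cx$model, "chain A", "chain A"), "overlap")
})

test_that("epitope counts match enumeration on an irregular toy complex", {
  m <- toy_model(data.frame(
    chain = c("A", "A", "A", "B", "B"),
    resid = c(1, 2, 3, 1, 2),
    name = "CA", element = "C",
    x = c(0, 4, 8, 1, 8.5), y = c(0, 0, 0, 3, 3), z = 0))
  ep <- epitope_map(m, "chain A", "chain B", cutoff = 4.5)
  ia <- resolve_selection(m, "chain A")
  ib <- resolve_selection(m, "chain B")
  oracle <- brute_pairs(coords(m)[ia, ], coords(m)[ib, ], 4.5)
  counts <- table(oracle$i)
  expect_equal(ep$residue_key, as.character(as.integer(names(counts))))
  expect_equal(ep$n_contacts, as.integer(counts), ignore_attr = TRUE)
})

test_that("competition is detected through superposition plus clash scan", {
  cx <- make_complex(seed = 1, epitope = c(10, 11, 12))
  # reference with a competitor on the same epitope: identical construction
  ref <- make_complex(seed = 99, epitope = c(10, 11, 12))
  res <- competition_assessment(cx$model, ref$model,
                                shared_antigen_sel = "chain A",
                                antibody_sel = "chain H L",
                                competitor_sel = "chain H L")
  expect_true(res$competes)
  expect_lt(res$fit_rmsd, 1e-9)
  # competitor on a distant epitope (resting beads offset so only the
  # epitopes could ever collide): no competition
  ref2 <- make_complex(seed = 99, epitope = c(40, 41, 42), binder_y = 90)
  res2 <- competition_assessment(cx$model, ref2$model,
                                 shared_antigen_sel = "chain A",
                                 antibody_sel = "chain H L",
                                 competitor_sel = "chain H L")
  expect_false(res2$competes)
})

test_that("borderline separations flip with the clash cutoff", {
  helix <- make_complex(seed = 1, n_heavy = 1, n_light = 1,
                        epitope = integer(0))$model
  ab <- helix$atoms
  # antibody atom (chain H) at a fixed spot; competitor (in the reference
  # copy) placed 3.05 A away from it
  ab$x[ab$chain_id == "H"] <- 30; ab$y[ab$chain_id == "H"] <- 30
  ab$z[ab$chain_id == "H"] <- 0
  ref <- ab
  ref$x[ref$chain_id == "L"] <- 30 + 3.05
  ref$y[ref$chain_id == "L"] <- 30; ref$z[ref$chain_id == "L"] <- 0
  m_ab <- structure_model(ab); m_ref <- structure_model(ref)
  d <- sqrt(sum((unlist(ab[ab$chain_id == "H", c("x", "y", "z")]) -
                 unlist(ref[ref$chain_id == "L", c("x", "y", "z")]))^2))
  expect_equal(d, 3.05)
  at30 <- competition_assessment(m_ab, m_ref, "chain A", "chain H",
                                 "chain L", clash_cutoff = 3.0)
  expect_false(at30$competes)
  at31 <- competition_assessment(m_ab, m_ref, "chain A", "chain H",
                                 "chain L", clash_cutoff = 3.1)
  expect_true(at31$competes)
})
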