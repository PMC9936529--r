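# Subsampling, balancing, fitted RMSD, ensemble statistics, plateau, RMSF,
# contacts, hydrogen bonds, percent differences.

static_traj <- function(model, times) {
  trajectory(model, rep(list(coords(model)), length(times)),
             frame_times = times)
}

test_that("subsampling keeps the first frame at or after each interval", {
  m <- make_complex(seed = 1, n_antigen = 4, n_heavy = 1, n_light = 1,
                    epitope = integer(0), low_nterm = 0)$model
  tr <- static_traj(m, seq(0, 5, by = 0.1))
  out <- subsample(tr, interval = 1)
  expect_equal(out$frame_times, 0:5)
  # interval finer than native spacing leaves the trajectory unchanged
  tr2 <- static_traj(m, 0:10)
  expect_equal(subsample(tr2, 0.5)$frame_times, 0:10)
  # single frame
  tr3 <- static_traj(m, 0)
  expect_equal(n_frames(subsample(tr3)), 1)
  expect_error(subsample(tr2, 0), "positive")
  # irregular grid: marks at 0,1,2 pick the first frame at/after each
  tr4 <- static_traj(m, c(0, 0.4, 1.3, 1.7, 2.6))
  expect_equal(subsample(tr4, 1)$frame_times, c(0, 1.3, 2.6))
})

test_that("balanced selection equalises frame counts across replicas", {
  m <- make_complex(seed = 1, n_antigen = 4, n_heavy = 1, n_light = 1,
                    epitope = integer(0), low_nterm = 0)$model
  r1 <- static_traj(m, seq(0, 1000, by = 1))   # 1000 ns replica
  r2 <- static_traj(m, seq(0, 998, by = 1))    # shorter replica
  bal <- balanced_frames(replica_ensemble(list(r1, r2)))
  counts <- vapply(bal$replicas, n_frames, integer(1))
  expect_equal(counts, c(999, 999))  # 998 intervals + frame 0
  expect_true(length(unique(counts)) == 1)
  # equal-length replicas unchanged
  bal2 <- balanced_frames(replica_ensemble(list(r2, r2)))
  expect_equal(vapply(bal2$replicas, n_frames, integer(1)), c(999, 999))
  # a single replica is identity up to subsampling
  bal3 <- balanced_frames(replica_ensemble(list(r1)))
  expect_equal(n_frames(bal3$replicas[[1]]), 1001)
})

test_that("antigen-fitted RMSD is zero for the reference itself and exact
           for a rigid binder translation", {
  cx <- make_complex(seed = 2, n_antigen = 15, n_heavy = 4, n_light = 4,
                     epitope = 5, low_nterm = 0)
  m <- cx$model
  tr <- static_traj(m, 0:4)
  rs <- fitted_rmsd_series(tr, reference = coords(m),
                           fit_sel = "chain A and CA",
                           calc_sel = "chain H L")
  expect_equal(rs$value, rep(0, 5), tolerance = 1e-10)

  # binder rigidly translated 5 A, antigen static -> constant 5.0
  shift <- coords(m)
  idx <- resolve_selection(m, "chain H L")
  shift[idx, 1] <- shift[idx, 1] + 5
  tr2 <- trajectory(m, rep(list(shift), 3), frame_times = 0:2)
  rs2 <- fitted_rmsd_series(tr2, reference = coords(m),
                            fit_sel = "chain A and CA",
                            calc_sel = "chain H L")
  expect_equal(rs2$value, rep(5, 3), tolerance = 1e-9)
})

test_that("per-frame RMSD values match an independent numerical oracle", {
  cx <- make_complex(seed = 3, n_antigen = 10, n_heavy = 3, n_light = 3,
                     epitope = 4, low_nterm = 0)
  m <- cx$model
  ens <- make_ensemble(m, seed = 7, n_replicas = 1, n_frames = 3,
                       sigma = 0.6)
  tr <- ens$ensemble$replicas[[1]]
  ifit <- resolve_selection(m, "chain A and CA")
  icalc <- resolve_selection(m, "chain H L")
  rs <- fitted_rmsd_series(tr, reference = coords(m),
                           fit_sel = "chain A and CA",
                           calc_sel = "chain H L")
  for (i in 1:3) {
    f <- frame_coords(tr, i)
    # oracle: numerically minimise the fit-atom RMSD, then measure calc
    # atoms under the optimal motion found by a generic optimiser
    rot <- function(ang) {
      cx_ <- cos(ang[1]); sx <- sin(ang[1]); cy <- cos(ang[2])
      sy <- sin(ang[2]); cz <- cos(ang[3]); sz <- sin(ang[3])
      matrix(c(cz * cy, cz * sy * sx - sz * cx_, cz * sy * cx_ + sz * sx,
               sz * cy, sz * sy * sx + cz * cx_, sz * sy * cx_ - cz * sx,
               -sy, cy * sx, cy * cx_), 3, byrow = TRUE)
    }
    obj <- function(par) {
      moved <- sweep(f[ifit, ] %*% t(rot(par[1:3])), 2, par[4:6], "+")
      sqrt(mean(rowSums((moved - coords(m)[ifit, ])^2)))
    }
    best <- NULL; bestv <- Inf
    for (k in 1:8) {
      set.seed(100 * i + k)
      p0 <- c(stats::runif(3, -0.3, 0.3),
              colMeans(coords(m)[ifit, ]) - colMeans(f[ifit, ]))
      o <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
      if (o$value < bestv) { bestv <- o$value; best <- o$par }
    }
    moved_calc <- sweep(f[icalc, ] %*% t(rot(best[1:3])), 2, best[4:6], "+")
    oracle <- sqrt(mean(rowSums((moved_calc - coords(m)[icalc, ])^2)))
    expect_equal(rs$value[i], oracle, tolerance = 1e-4)
  }
})

test_that("fitted RMSD is invariant under a global rigid transform", {
  cx <- make_complex(seed = 4, n_antigen = 12, n_heavy = 3, n_light = 3,
                     epitope = 6, low_nterm = 0)
  ens <- make_ensemble(cx$model, seed = 9, n_replicas = 1, n_frames = 5,
                       sigma = 0.4)
  tr <- ens$ensemble$replicas[[1]]
  base <- fitted_rmsd_series(tr, reference = coords(cx$model),
                             fit_sel = "chain A and CA",
                             calc_sel = "chain H L")
  ang <- 1.1
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, byrow = TRUE)
  moved <- tr$frames
  for (i in seq_len(dim(moved)[1])) {
    moved[i, , ] <- sweep(tr$frames[i, , ] %*% t(R), 2, c(12, -7, 30), "+")
  }
  tr2 <- trajectory(tr$topology, moved, frame_times = tr$frame_times)
  rs2 <- fitted_rmsd_series(tr2, reference = coords(cx$model),
                            fit_sel = "chain A and CA",
                            calc_sel = "chain H L")
  expect_equal(rs2$value, base$value, tolerance = 1e-9)
})

test_that("ensemble statistics compute the replica mean and SEM", {
  ts <- function(v) time_series(0, v)
  # ten identical series: sem exactly zero
  es <- ensemble_stats(rep(list(time_series(0:2, c(4, 4, 4))), 10))
  expect_equal(es$mean, rep(4, 3))
  expect_equal(es$sem, rep(0, 3))
  # two values 1 and 3: mean 2, sd sqrt(2), sem 1
  es2 <- ensemble_stats(list(ts(1), ts(3)))
  expect_equal(es2$mean, 2)
  expect_equal(es2$sem, 1)
  # single replica: sem reported missing
  es3 <- ensemble_stats(list(time_series(0:1, c(1, 2))))
  expect_equal(es3$mean, c(1, 2))
  expect_true(all(is.na(es3$sem)))
  expect_error(ensemble_stats(list(time_series(0:1, 1:2),
                                   time_series(0:2, 1:3))),
               "time grid")
  # sem is zero iff replicas agree at that point
  es4 <- ensemble_stats(list(time_series(0:1, c(1, 5)),
                             time_series(0:1, c(1, 7))))
  expect_equal(es4$sem[1], 0)
  expect_gt(es4$sem[2], 0)
})

test_that("plateau summary averages the final window", {
  const <- ensemble_stats(rep(list(time_series(0:100, rep(7, 101))), 3))
  pv <- plateau_value(const, window = 20)
  expect_equal(pv$mean, 7)
  expect_equal(pv$sem, 0)
  # linear ramp 0 -> 100 over 1000 ns, window 200: mean over [800, 1000]
  tgrid <- seq(0, 1000, by = 1)
  ramp <- time_series(tgrid, tgrid / 10)
  es <- ensemble_stats(list(ramp, ramp))
  pv2 <- plateau_value(es, window = 200)
  expect_equal(pv2$mean, mean(tgrid[tgrid >= 800] / 10))
  # window longer than the span: whole-series mean with a warning
  expect_warning(pv3 <- plateau_value(es, window = 5000), "whole series")
  expect_equal(pv3$mean, mean(tgrid / 10))
})

test_that("RMSF is zero for static trajectories and exact for a two-frame
           displacement", {
  cx <- make_complex(seed = 5, n_antigen = 10, n_heavy = 2, n_light = 2,
                     epitope = integer(0), low_nterm = 0)
  m <- cx$model
  tr <- static_traj(m, 0:3)
  rf <- rmsf_com(tr, fit_sel = "chain A and CA")
  expect_equal(rf$rmsf, rep(0, nrow(rf)), tolerance = 1e-10)
  # one binder residue displaced +/- 1 A about its mean along x
  f1 <- coords(m); f2 <- coords(m)
  idx <- resolve_selection(m, "chain H and resid 1")
  f1[idx, 1] <- f1[idx, 1] + 1
  f2[idx, 1] <- f2[idx, 1] - 1
  tr2 <- trajectory(m, list(f1, f2), frame_times = 0:1)
  rf2 <- rmsf_com(tr2, fit_sel = "chain A and CA")
  expect_equal(rf2$rmsf[rf2$chain_id == "H" & rf2$residue_key == "1"], 1.0,
               tolerance = 1e-9)
  expect_equal(max(rf2$rmsf[rf2$chain_id == "A"]), 0, tolerance = 1e-9)
  expect_error(rmsf_com(static_traj(m, 0), fit_sel = "chain A and CA"),
               "2 frames")
})

test_that("contact counting is strict, heavy-atom only, oracle-exact", {
  pair <- function(d, elemB = "C") {
    toy_model(data.frame(chain = c("A", "B"), resid = 1,
                         name = c("CA", if (elemB == "H") "H1" else "CA"),
                         element = c("C", elemB), x = c(0, d), y = 0, z = 0))
  }
  m44 <- pair(4.4)
  expect_equal(contact_count(coords(m44), m44, "chain A", "chain B"), 1)
  m45 <- pair(4.5)   # exactly at the cutoff: "closer than" excludes it
  expect_equal(contact_count(coords(m45), m45, "chain A", "chain B"), 0)
  mh <- pair(1.0, elemB = "H")  # hydrogen neighbours never count
  expect_equal(contact_count(coords(mh), mh, "chain A", "chain B"), 0)
  m <- random_cloud_model(50, seed = 3)
  ia <- resolve_selection(m, "chain A"); ib <- resolve_selection(m, "chain B")
  oracle <- nrow(brute_pairs(coords(m)[ia, ], coords(m)[ib, ], 4.5))
  expect_equal(contact_count(coords(m), m, "chain A", "chain B"), oracle)
  expect_error(contact_count(coords(m), m, "chain A", "all"), "overlap")
})

test_that("hydrogen bonds require both distance and angle", {
  hb <- function(d, ang) {
    out <- make_hbond_lattice(distances = d, angles = ang)
    hbond_count(coords(out$model), out$model, "chain D", "chain C")
  }
  expect_equal(hb(3.4, 170), 1)
  expect_equal(hb(3.4, 140), 0)   # angle fails alone
  expect_equal(hb(3.6, 180), 0)   # distance fails alone
  expect_equal(hb(3.5, 150), 1)   # both limits inclusive
})

test_that("contact and hydrogen-bond counts equal brute force on random
           geometries", {
  for (s in 1:25) {
    m <- random_cloud_model(24, seed = 1000 + s, spread = 10)
    ia <- resolve_selection(m, "chain A")
    ib <- resolve_selection(m, "chain B")
    expect_equal(contact_count(coords(m), m, "chain A", "chain B",
                               cutoff = 4.5),
                 nrow(brute_pairs(coords(m)[ia, ], coords(m)[ib, ], 4.5)))
    lat <- make_hbond_lattice(
      distances = stats::runif(6, 2.5, 4.5),
      angles = stats::runif(6, 100, 180), seed = s)
    expect_equal(hbond_count(coords(lat$model), lat$model,
                             "chain D", "chain C"),
                 brute_hbonds(coords(lat$model), lat$model,
                              resolve_selection(lat$model, "chain D"),
                              resolve_selection(lat$model, "chain C")))
  }
})

test_that("interface series aggregate per-frame counts across replicas", {
  cxA <- make_complex(seed = 1, epitope = 1:10)
  cxB <- make_complex(seed = 1, epitope = 1:20)
  mkrep <- function(cx) trajectory(cxA$model,
                                   rep(list(coords(cx$model)), 4),
                                   frame_times = 0:3)
  ens <- replica_ensemble(list(mkrep(cxA), mkrep(cxB)))
  es <- interface_series(ens, "contacts", "chain A", "chain H L")
  expect_equal(es$values[, 1], rep(10, 4))
  expect_equal(es$values[, 2], rep(20, 4))
  expect_equal(es$mean, rep(15, 4))
  # static ensemble: constant series equal to the frame-0 count
  st <- replica_ensemble(list(mkrep(cxA)))
  es2 <- interface_series(st, "contacts", "chain A", "chain H L")
  expect_equal(es2$values[, 1],
               rep(contact_count(coords(cxA$model), cxA$model,
                                 "chain A", "chain H L"), 4))
  # hydrogen-bond metric flows through the same aggregation
  lat <- make_hbond_lattice(distances = c(3.0, 3.0, 3.8),
                            angles = c(170, 120, 170))
  hb_ens <- replica_ensemble(list(
    trajectory(lat$model, rep(list(coords(lat$model)), 3),
               frame_times = 0:2)))
  es3 <- interface_series(hb_ens, "hbonds", "chain D", "chain C")
  expect_equal(es3$values[, 1], rep(lat$expected, 3))
  expect_equal(lat$expected, 1L)
})

test_that("percent difference uses replica-mean aggregation", {
  mk <- function(v) ensemble_stats(lapply(v, function(x)
    time_series(0:4, rep(x, 5))))
  expect_equal(percent_difference(mk(c(18.5, 18.5)), mk(c(10, 10))), 85)
  expect_equal(percent_difference(mk(c(7, 7)), mk(c(7, 7))), 0)
  # replica means are weighted equally (not pooled frames)
  a <- ensemble_stats(list(time_series(0:1, c(2, 4)),
                           time_series(0:1, c(10, 10))))
  expect_equal(percent_difference(a, mk(c(5, 5))), 100 * (6.5 - 5) / 5)
  expect_error(percent_difference(mk(c(1, 1)), mk(c(0, 0))), "zero")
})
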