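# Seeded generators for every input class the pipeline consumes, each
# returning its own analytically known ground truth. They emulate, at toy
# scale, the study conditions of the real workflow: predicted three-chain
# antibody-antigen complexes with per-residue confidence and pTM/PAE scores,
# replica MD ensembles with isotropic Gaussian fluctuations and optional
# rigid drift, hydrogen-bond geometries with exact expected counts, and
# multi-concentration bivalent sensorgrams with additive noise.
#
# RNG discipline: every generator takes an integer seed, seeds R's default
# Mersenne-Twister stream once on entry and restores the caller's RNG state
# on exit, so outputs are bit-for-bit reproducible and generators do not
# perturb each other.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

.bead_atoms <- function(chain_id, n_res, origin, step, resname = "ALA",
                        serial0 = 0L) {
  i <- seq_len(n_res)
  data.frame(
    serial = serial0 + i,
    name = "CA",
    element = "C",
    x = origin[1] + (i - 1) * step[1],
    y = origin[2] + (i - 1) * step[2],
    z = origin[3] + (i - 1) * step[3],
    chain_id = chain_id,
    residue_index = i,
    ins = "",
    residue_name = resname,
    occupancy = 1.0,
    bfactor = 85.0,
    stringsAsFactors = FALSE)
}

# Helical bead chain: a genuinely three-dimensional arrangement so that a
# least-squares fit on these atoms constrains all six rigid degrees of
# freedom (a straight chain would leave the roll about its axis free).
# radius 10 A, 0.6 rad per residue and 1.5 A rise give a ~6.1 A step
# between consecutive beads.
.helix_atoms <- function(chain_id, n_res, serial0 = 0L, radius = 10,
                         turn = 0.6, rise = 1.5, resname = "ALA") {
  i <- seq_len(n_res)
  th <- (i - 1) * turn
  data.frame(
    serial = serial0 + i,
    name = "CA",
    element = "C",
    x = radius * cos(th),
    y = radius * sin(th),
    z = (i - 1) * rise,
    chain_id = chain_id,
    residue_index = i,
    ins = "",
    residue_name = resname,
    occupancy = 1.0,
    bfactor = 85.0,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic antibody-antigen complex with known epitope
#'
#' Builds a three-chain bead model (antigen chain `A`, heavy chain `H`,
#' light chain `L`; one C-alpha bead per residue) in which exactly the
#' requested epitope residues of the antigen have a heavy-atom pair within
#' the contact cutoff: the contacting binder bead sits 3.8 Angstrom
#' radially outward of its epitope residue, and the antigen is a helix
#' (6.1 Angstrom bead spacing) so neighbouring residues stay outside the
#' 4.5 Angstrom contact cutoff and a least-squares fit on the antigen
#' constrains all six rigid degrees of freedom. All other binder beads are
#' tens of Angstrom away. Also fabricates a per-chain pLDDT profile with
#' configurable low-confidence terminal runs on the antigen, and a pTM/PAE
#' score record with distinct intra- and inter-chain blocks.
#'
#' @param seed integer seed (fixes all outputs bit-for-bit).
#' @param n_antigen,n_heavy,n_light residues per chain (defaults 60/50/50).
#' @param epitope integer vector of antigen residue indices that must be in
#'   contact (default `c(10, 11, 12)`). Contacts alternate between the
#'   heavy and light chain.
#' @param low_nterm,low_cterm number of low-confidence (pLDDT < 70)
#'   residues at the antigen N-/C-terminus (defaults 2 and 0); their values
#'   ramp from 50 upward, all below 70.
#' @param binder_y resting y-offset (Angstrom) of the non-contacting
#'   binder beads (default 60); distinct offsets keep two generated
#'   complexes from overlapping anywhere except their epitopes.
#' @param ptm pTM score of the fabricated model (default 0.842).
#' @param pae_intra,pae_inter PAE block values in Angstrom (defaults 3 and
#'   10).
#' @return list with `model` ([structure_model()]), `profile` (per-chain
#'   pLDDT list), `score` ([model_score()]) and `ground_truth` (list with
#'   `epitope` and the trim counts).
#' @export
make_complex <- function(seed = 1, n_antigen = 60, n_heavy = 50,
                         n_light = 50, epitope = c(10, 11, 12),
                         low_nterm = 2, low_cterm = 0, binder_y = 60,
                         ptm = 0.842, pae_intra = 3, pae_inter = 10) {
  stopifnot(all(epitope >= 1), all(epitope <= n_antigen))
  if (length(epitope) > n_heavy + n_light) {
    stop("infeasible epitope: more epitope residues than binder residues")
  }
  .with_seed(seed, {
    ag <- .helix_atoms("A", n_antigen)
    hc <- .bead_atoms("H", n_heavy, c(0, binder_y, 12), c(4.8, 0, 0),
                      serial0 = n_antigen)
    lc <- .bead_atoms("L", n_light, c(0, binder_y, -12), c(4.8, 0, 0),
                      serial0 = n_antigen + n_heavy)
    # place one binder bead 3.8 A radially outward of each epitope residue
    # (alternating between heavy and light chain); the outward direction
    # keeps every non-epitope antigen bead > 4.5 A away
    for (k in seq_along(epitope)) {
      r <- epitope[k]
      u <- c(ag$x[r], ag$y[r], 0)
      u <- u / sqrt(sum(u^2))
      pos <- c(ag$x[r], ag$y[r], ag$z[r]) + 3.8 * u
      if (k %% 2 == 1) {
        j <- (k + 1) %/% 2
        hc$x[j] <- pos[1]; hc$y[j] <- pos[2]; hc$z[j] <- pos[3]
      } else {
        j <- k %/% 2
        lc$x[j] <- pos[1]; lc$y[j] <- pos[2]; lc$z[j] <- pos[3]
      }
    }
    # low-confidence terminal runs on the antigen
    plddt_a <- rep(85, n_antigen)
    if (low_nterm > 0) {
      plddt_a[seq_len(low_nterm)] <- seq(50, 65,
                                         length.out = low_nterm)
    }
    if (low_cterm > 0) {
      plddt_a[n_antigen - seq_len(low_cterm) + 1] <-
        seq(50, 65, length.out = low_cterm)
    }
    ag$bfactor <- plddt_a
    atoms <- rbind(ag, hc, lc)
    model <- structure_model(atoms, model_id = sprintf("synth-%d", seed),
                             source_format = "synthetic")
    n_res <- n_antigen + n_heavy + n_light
    pae <- matrix(pae_inter, n_res, n_res)
    blocks <- list(A = seq_len(n_antigen),
                   H = n_antigen + seq_len(n_heavy),
                   L = n_antigen + n_heavy + seq_len(n_light))
    for (b in blocks) pae[b, b] <- pae_intra
    score <- model_score(model$model_id, ptm = ptm, pae = pae)
    list(model = model,
         profile = plddt_profile(model),
         score = score,
         ground_truth = list(epitope = epitope, low_nterm = low_nterm,
                             low_cterm = low_cterm,
                             chain_residues = blocks))
  })
}

#' Generate a replica ensemble with known fluctuation ground truth
#'
#' Each replica is the base pose plus independent per-atom isotropic
#' Gaussian jitter (per-axis standard deviation `sigma`), optionally with a
#' rigid drift of the binder chains growing linearly in time. Expected
#' per-residue center-of-mass RMSF for jittered single-bead residues is
#' `sigma * sqrt(3)`; the expected antigen-fitted RMSD of a drifted binder
#' grows as `|drift| * t`.
#'
#' @param model base [structure_model()] (e.g. from [make_complex()]).
#' @param seed integer seed.
#' @param n_replicas number of replicas, default 10.
#' @param n_frames frames per replica, default 100.
#' @param dt frame spacing in ns, default 1.
#' @param sigma per-axis Gaussian fluctuation width, Angstrom (default
#'   0.5).
#' @param jitter_chains chains the jitter applies to; `NULL` (default)
#'   jitters every atom. Restricting the jitter to non-fit chains keeps
#'   the superposition frame exact, which makes the `sigma * sqrt(3)` RMSF
#'   expectation hold exactly (jittered fit atoms add lever-arm noise
#'   through the fit itself).
#' @param drift length-3 drift velocity of the binder chains, Angstrom/ns
#'   (default none).
#' @param drift_chains chains the drift applies to, default `c("H", "L")`.
#' @return list with `ensemble` ([replica_ensemble()]) and `ground_truth`
#'   (list with `sigma`, `drift`, `expected_rmsf`).
#' @export
make_ensemble <- function(model, seed = 1, n_replicas = 10, n_frames = 100,
                          dt = 1, sigma = 0.5, jitter_chains = NULL,
                          drift = c(0, 0, 0),
                          drift_chains = c("H", "L")) {
  stopifnot(inherits(model, "structure_model"), sigma >= 0,
            length(drift) == 3, n_frames >= 1, n_replicas >= 1)
  .with_seed(seed, {
    x0 <- coords(model)
    na <- nrow(x0)
    idx_drift <- which(model$atoms$chain_id %in% drift_chains)
    idx_jit <- if (is.null(jitter_chains)) seq_len(na)
               else which(model$atoms$chain_id %in% jitter_chains)
    times <- (seq_len(n_frames) - 1) * dt
    reps <- lapply(seq_len(n_replicas), function(r) {
      frames <- array(0, dim = c(n_frames, na, 3))
      for (i in seq_len(n_frames)) {
        f <- x0
        if (sigma > 0 && length(idx_jit) > 0) {
          f[idx_jit, ] <- f[idx_jit, , drop = FALSE] +
            matrix(stats::rnorm(length(idx_jit) * 3, 0, sigma),
                   length(idx_jit), 3)
        }
        if (any(drift != 0) && length(idx_drift) > 0) {
          f[idx_drift, ] <- sweep(f[idx_drift, , drop = FALSE], 2,
                                  drift * times[i], "+")
        }
        frames[i, , ] <- f
      }
      trajectory(model, frames, frame_times = times)
    })
    list(ensemble = replica_ensemble(reps, complex_label = model$model_id),
         ground_truth = list(sigma = sigma, drift = drift,
                             expected_rmsf = sigma * sqrt(3),
                             jitter_chains = jitter_chains,
                             drift_chains = drift_chains))
  })
}

#' Generate isolated donor-hydrogen-acceptor triples with exact geometry
#'
#' Places one donor (N), its hydrogen (1.0 Angstrom away) and one acceptor
#' (O) per requested geometry, each triple 100 Angstrom from the next so
#' triples cannot interact. The acceptor is positioned so the
#' donor-acceptor distance and the three-point angle at the hydrogen are
#' exactly the requested values, giving an exact expected hydrogen-bond
#' count under the default criteria (distance <= 3.5 Angstrom, angle >=
#' 150 degrees).
#'
#' @param distances donor-acceptor heavy-atom distances, Angstrom
#'   (recycled against `angles`).
#' @param angles D-H...A angles at the hydrogen, degrees.
#' @param seed integer seed (the construction is deterministic; the seed
#'   only fixes the stored spec).
#' @param criteria an [hbond_criteria()] used to compute the expected
#'   count.
#' @return list with `model` (donors chain `D`, acceptors chain `C`),
#'   `expected` (exact count) and `geometries` (the per-triple table).
#' @export
make_hbond_lattice <- function(distances = rep(3.0, 6),
                               angles = rep(175, 6), seed = 1,
                               criteria = hbond_criteria()) {
  n <- max(length(distances), length(angles))
  distances <- rep_len(distances, n)
  angles <- rep_len(angles, n)
  stopifnot(all(distances > 1), all(angles > 0), all(angles <= 180))
  don <- vector("list", n); acc <- vector("list", n)
  dh <- 1.0
  for (i in seq_len(n)) {
    ox <- 100 * (i - 1)
    d <- distances[i]; th <- angles[i] * pi / 180
    # donor at origin, H along +x; acceptor in the xy-plane making the
    # requested three-point angle at H with |DA| = d
    ha <- dh * cos(th) + sqrt(d^2 - dh^2 * sin(th)^2)
    hx <- dh
    # H->D direction is (-1, 0, 0); the acceptor direction makes angle th
    # with it in the xy-plane
    adir <- c(-cos(th), sin(th), 0)
    apos <- c(hx, 0, 0) + ha * adir
    don[[i]] <- data.frame(
      serial = c(2L * i - 1L, 2L * i),
      name = c("N", "H1"),
      element = c("N", "H"),
      x = ox + c(0, hx), y = c(0, 0), z = c(0, 0),
      chain_id = "D", residue_index = i, ins = "",
      residue_name = "GLN", occupancy = 1, bfactor = 0,
      stringsAsFactors = FALSE)
    acc[[i]] <- data.frame(
      serial = 1000L + i, name = "O", element = "O",
      x = ox + apos[1], y = apos[2], z = apos[3],
      chain_id = "C", residue_index = i, ins = "",
      residue_name = "SER", occupancy = 1, bfactor = 0,
      stringsAsFactors = FALSE)
  }
  atoms <- rbind(do.call(rbind, don), do.call(rbind, acc))
  model <- structure_model(atoms, model_id = sprintf("hbond-%d", seed),
                           source_format = "synthetic")
  expected <- sum(distances <= criteria$da_cutoff + 1e-9 &
                  angles >= criteria$angle_min - 1e-9)
  list(model = model, expected = as.integer(expected),
       geometries = data.frame(distance = distances, angle = angles))
}

#' Generate multi-concentration sensorgrams with known rate constants
#'
#' Simulates the chosen kinetic model at each analyte concentration and
#' adds seeded Gaussian noise with standard deviation `noise_frac * Bmax1`,
#' returning the generating parameters as ground truth for
#' parameter-recovery tests. Defaults emulate a three-concentration
#' injection series (2.5, 5 and 10 nM).
#'
#' @param params generating [bivalent_params()]. The default is an
#'   identifiable nanomolar antibody-antigen regime: both binding steps
#'   evolve on timescales observable within the injection design
#'   (`ka1 * C` and `kd1` of order 1e-3 1/s, the second step neither
#'   negligible nor rebinding-dominated, `ka2 * Bmax ~ kd1`), so that
#'   every rate constant leaves a distinct signature in the curves.
#' @param concs analyte concentrations in M, default
#'   `c(2.5e-9, 5e-9, 10e-9)`.
#' @param t_assoc association duration, s (default 300).
#' @param t_total total duration, s (default 1200; the long dissociation
#'   tail resolves the slow second-step release).
#' @param dt sampling interval, s (default 2).
#' @param noise_frac Gaussian noise SD as a fraction of Bmax1 (default
#'   0.01).
#' @param seed integer seed.
#' @param model `"bivalent"` (default) or `"two_site"`.
#' @return list with `sensorgrams` (list of `sensorgram`), `params`
#'   (ground truth) and `model`.
#' @export
make_sensorgrams <- function(params = bivalent_params(
                               ka1 = 2e5, kd1 = 2e-3, ka2 = 5e-5,
                               kd2 = 5e-4, Bmax1 = 100, Bmax2 = 30),
                             concs = c(2.5e-9, 5e-9, 10e-9),
                             t_assoc = 300, t_total = 1200, dt = 2,
                             noise_frac = 0.01, seed = 1,
                             model = c("bivalent", "two_site")) {
  model <- match.arg(model)
  times <- seq(0, t_total, by = dt)
  .with_seed(seed, {
    sgs <- lapply(concs, function(cc) {
      sg <- .simulate_core(params, cc, times, t_assoc, model)
      if (noise_frac > 0) {
        sg$response <- sg$response +
          stats::rnorm(nrow(sg), 0, noise_frac * params$Bmax1)
      }
      sg
    })
    list(sensorgrams = sgs, params = params, model = model)
  })
}
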