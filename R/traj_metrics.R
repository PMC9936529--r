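# Trajectory analyses: subsampling, replica-balanced frame selection,
# antigen-fitted RMSD, ensemble mean +/- SEM, plateau summaries, per-residue
# center-of-mass RMSF, contact and hydrogen-bond counting, and
# percent-difference comparison between complexes.

#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is counted when the donor and acceptor heavy atoms are at
#' most `da_cutoff` apart (inclusive) and the three-point angle at the
#' donor hydrogen between the donor and the acceptor is at least
#' `angle_min`. The near-linear band often quoted as 150-210 degrees is the
#' symmetric region |theta - 180| <= 30 of a three-point angle, which cannot
#' exceed 180 degrees, hence a single lower bound.
#'
#' @param da_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 150).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, angle_min = 150) {
  stopifnot(da_cutoff > 0, angle_min > 0, angle_min <= 180)
  structure(list(da_cutoff = da_cutoff, angle_min = angle_min),
            class = "hbond_criteria")
}

#' Construct a labelled time series
#'
#' @param times numeric vector, ns, strictly increasing.
#' @param values numeric vector of equal length.
#' @param label optional label string.
#' @return object of class `time_series` (a data.frame with columns `time`
#'   and `value`).
#' @export
time_series <- function(times, values, label = "") {
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  out <- data.frame(time = as.numeric(times), value = as.numeric(values))
  attr(out, "label") <- label
  class(out) <- c("time_series", "data.frame")
  out
}

#' Subsample a trajectory on a regular interval
#'
#' Keeps, for each multiple of `interval` up to the final frame time, the
#' first frame at or after that multiple. Frame times are preserved.
#'
#' @param traj a [trajectory()].
#' @param interval sampling interval in ns, default 1.
#' @return the subsampled [trajectory()].
#' @export
subsample <- function(traj, interval = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(interval) || interval <= 0) {
    stop("interval must be positive")
  }
  t <- traj$frame_times
  marks <- seq(0, max(t) + 1e-9, by = interval)
  idx <- unique(vapply(marks, function(m) {
    which(t >= m - 1e-9)[1]
  }, integer(1)))
  idx <- idx[!is.na(idx)]
  trajectory(traj$topology, traj$frames[idx, , , drop = FALSE],
             frame_times = t[idx])
}

#' Replica-balanced frame selection
#'
#' Subsamples every replica on the same interval and truncates all replicas
#' to the minimum frame count, so each simulation contributes an equal
#' number of frames to ensemble statistics (no statistical bias toward
#' longer runs).
#'
#' @param ensemble a [replica_ensemble()].
#' @param interval sampling interval in ns, default 1.
#' @return a balanced [replica_ensemble()].
#' @export
balanced_frames <- function(ensemble, interval = 1) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  subs <- lapply(ensemble$replicas, subsample, interval = interval)
  nmin <- min(vapply(subs, n_frames, integer(1)))
  trimmed <- lapply(subs, function(tr) {
    trajectory(tr$topology, tr$frames[seq_len(nmin), , , drop = FALSE],
               frame_times = tr$frame_times[seq_len(nmin)])
  })
  replica_ensemble(trimmed, complex_label = ensemble$complex_label)
}

#' Antigen-fitted RMSD time series
#'
#' For each frame, superposes the frame onto the reference using the fit
#' selection (least-squares rigid fit), then computes the RMSD of the
#' calculation selection (heavy atoms) alone. Fitting on the antigen and
#' measuring the bound antibody quantifies how stably the antibody stays in
#' its pose.
#'
#' @param traj a [trajectory()].
#' @param reference `n_atoms x 3` reference coordinates compatible with the
#'   trajectory topology (defaults to frame 1).
#' @param fit_sel selection used for superposition (default `"CA"`; the fit
#'   atom set is configurable, e.g. `"heavy"`).
#' @param calc_sel selection over which the RMSD is computed; hydrogens are
#'   excluded.
#' @return a [time_series()] of RMSD values (Angstrom).
#' @export
fitted_rmsd_series <- function(traj, reference = NULL, fit_sel = "CA",
                               calc_sel) {
  stopifnot(inherits(traj, "trajectory"))
  model <- traj$topology
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  if (nrow(reference) != nrow(model$atoms)) {
    stop("reference coordinates do not match topology atom count")
  }
  ifit <- resolve_selection(model, fit_sel)
  icalc <- resolve_selection(model, calc_sel)
  icalc <- icalc[!model$atoms$is_hydrogen[icalc]]
  if (length(ifit) == 0 || length(icalc) == 0) {
    stop("empty fit or calc selection")
  }
  ref_calc <- reference[icalc, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    tf <- kabsch_superpose(x, reference, fit_mobile = ifit,
                           fit_reference = ifit)
    fitted <- apply_transform(x[icalc, , drop = FALSE], tf)
    sqrt(mean(rowSums((fitted - ref_calc)^2)))
  }, numeric(1))
  time_series(traj$frame_times, vals, label = "fitted RMSD (A)")
}

#' Ensemble mean and standard error across replicas
#'
#' @param series list of [time_series()] objects on an identical time grid
#'   (one per replica).
#' @return object of class `ensemble_series`: list with `times`, `values`
#'   (matrix, time x replica), `mean`, `sem` (sample standard deviation with
#'   n-1 denominator divided by sqrt(n); `NA` when there is a single
#'   replica) and `n_replicas`.
#' @export
ensemble_stats <- function(series) {
  stopifnot(is.list(series), length(series) >= 1)
  t0 <- series[[1]]$time
  for (s in series) {
    if (length(s$time) != length(t0) || any(abs(s$time - t0) > 1e-9)) {
      stop("all series must share one time grid")
    }
  }
  vals <- vapply(series, function(s) s$value, numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  n <- ncol(vals)
  mu <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n)
         else rep(NA_real_, length(t0))
  structure(list(times = t0, values = vals, mean = mu, sem = sem,
                 n_replicas = n),
            class = "ensemble_series")
}

#' @export
print.ensemble_series <- function(x, ...) {
  cat("ensemble_series: ", x$n_replicas, " replicas x ", length(x$times),
      " time points; final mean ",
      format(x$mean[length(x$mean)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plateau summary over the final time window
#'
#' Averages the ensemble over the last `window` ns (the plateau region of a
#' relaxed observable). The value is the time-average of the ensemble mean
#' in the window; the uncertainty is the standard error across the replica
#' window-means. If the window exceeds the series span it is clipped to the
#' whole series with a warning.
#'
#' @param series an [ensemble_stats()] result.
#' @param window window length in ns, default 200.
#' @return list with `mean` and `sem` (`NA` for a single replica).
#' @export
plateau_value <- function(series, window = 200) {
  stopifnot(inherits(series, "ensemble_series"))
  if (length(series$times) == 0) stop("empty series")
  tmax <- max(series$times)
  if (window > tmax - min(series$times)) {
    warning("window longer than series span; using the whole series")
    idx <- seq_along(series$times)
  } else {
    idx <- which(series$times >= tmax - window - 1e-9)
  }
  rep_means <- colMeans(series$values[idx, , drop = FALSE])
  list(mean = mean(rep_means),
       sem = if (length(rep_means) > 1)
         stats::sd(rep_means) / sqrt(length(rep_means)) else NA_real_)
}

# Superpose every frame of a frames array onto target coordinates using fit
# atom indices; returns the array of fitted frames.
.fit_frames <- function(frames, target, ifit) {
  out <- frames
  for (i in seq_len(dim(frames)[1])) {
    x <- frames[i, , ]
    dim(x) <- dim(frames)[2:3]
    tf <- kabsch_superpose(x, target, fit_mobile = ifit,
                           fit_reference = ifit)
    out[i, , ] <- apply_transform(x, tf)
  }
  out
}

#' Per-residue center-of-mass RMSF about the average structure
#'
#' Computes, for every residue, the root-mean-square fluctuation of its
#' center of mass about the average structure. The average structure is
#' obtained with a two-pass scheme: all frames are first fitted to the
#' initial frame and averaged, then re-fitted to that average and averaged
#' again; the final average is the fluctuation reference. Frames from all
#' replicas of an ensemble are pooled.
#'
#' @param x a [trajectory()] or [replica_ensemble()] with at least 2 frames
#'   in total.
#' @param fit_sel selection used for the superpositions (default `"CA"`).
#' @param mass_weighted weight residue centers by standard atomic masses
#'   (default `TRUE`).
#' @return object of class `rmsf_profile`: data.frame with `chain_id`,
#'   `residue_key`, `rmsf` (Angstrom).
#' @export
rmsf_com <- function(x, fit_sel = "CA", mass_weighted = TRUE) {
  if (inherits(x, "replica_ensemble")) {
    model <- x$replicas[[1]]$topology
    frames <- abind_frames(lapply(x$replicas, function(r) r$frames))
  } else if (inherits(x, "trajectory")) {
    model <- x$topology
    frames <- x$frames
  } else stop("x must be a trajectory or replica_ensemble")
  nf <- dim(frames)[1]
  if (nf < 2) stop("RMSF is undefined for fewer than 2 frames")
  ifit <- resolve_selection(model, fit_sel)
  if (length(ifit) < 3) stop("fit selection must resolve >= 3 atoms")

  # pass 1: fit to the first frame, average
  f0 <- frames[1, , ]; dim(f0) <- dim(frames)[2:3]
  fitted <- .fit_frames(frames, f0, ifit)
  avg1 <- apply(fitted, c(2, 3), mean)
  # pass 2: re-fit to that average, re-average
  fitted <- .fit_frames(frames, avg1, ifit)
  avg <- apply(fitted, c(2, 3), mean)

  a <- model$atoms
  rt <- .residue_table(model)
  akey <- paste(a$chain_id, a$residue_key, sep = "|")
  w <- if (mass_weighted) {
    m <- .ATOMIC_MASSES[a$element]
    if (anyNA(m)) stop("no standard atomic mass for element(s): ",
                       paste(unique(a$element[is.na(m)]), collapse = ", "))
    m
  } else rep(1, nrow(a))

  rmsf <- numeric(nrow(rt))
  for (r in seq_len(nrow(rt))) {
    idx <- which(akey == rt$key[r])
    wr <- w[idx] / sum(w[idx])
    com_avg <- colSums(avg[idx, , drop = FALSE] * wr)
    # residue COM per frame via weighted sums over the fitted array
    dx <- fitted[, idx, , drop = FALSE]
    com_t <- apply(dx, c(1, 3), function(v) sum(v * wr))
    dev2 <- rowSums(sweep(com_t, 2, com_avg)^2)
    rmsf[r] <- sqrt(mean(dev2))
  }
  out <- data.frame(chain_id = rt$chain_id, residue_key = rt$residue_key,
                    rmsf = rmsf, stringsAsFactors = FALSE)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

# Concatenate frame arrays along the frame axis.
abind_frames <- function(frame_list) {
  n <- vapply(frame_list, function(f) dim(f)[1], integer(1))
  d <- dim(frame_list[[1]])
  out <- array(0, dim = c(sum(n), d[2], d[3]))
  at <- 0L
  for (f in frame_list) {
    out[at + seq_len(dim(f)[1]), , ] <- f
    at <- at + dim(f)[1]
  }
  out
}

#' Count heavy-atom contacts between two groups in one frame
#'
#' A contact is two heavy (non-hydrogen) atoms, one from each group,
#' strictly closer than the cutoff.
#'
#' @param frame `n_atoms x 3` coordinate matrix aligned with `model`.
#' @param model a [structure_model()].
#' @param sel_a,sel_b disjoint selection expressions.
#' @param cutoff Angstrom, default 4.5.
#' @return integer contact count.
#' @export
contact_count <- function(frame, model, sel_a, sel_b, cutoff = 4.5) {
  ia <- resolve_selection(model, sel_a)
  ib <- resolve_selection(model, sel_b)
  if (length(intersect(ia, ib)) > 0) stop("selections overlap")
  ia <- ia[!model$atoms$is_hydrogen[ia]]
  ib <- ib[!model$atoms$is_hydrogen[ib]]
  if (length(ia) == 0 || length(ib) == 0) return(0L)
  nrow(.pairs_within(frame[ia, , drop = FALSE], frame[ib, , drop = FALSE],
                     cutoff, inclusive = FALSE))
}

#' Count geometric hydrogen bonds between donor and acceptor groups
#'
#' Donors are N/O heavy atoms of the donor selection carrying at least one
#' hydrogen within 1.2 Angstrom (geometric bond inference; donors without a
#' hydrogen are skipped). Acceptors are N/O heavy atoms of the acceptor
#' selection. A (donor, hydrogen, acceptor) triple is counted when the
#' donor-acceptor distance is at most `da_cutoff` (inclusive) and the
#' three-point angle at the hydrogen is at least `angle_min`.
#'
#' @param frame `n_atoms x 3` coordinate matrix aligned with `model`.
#' @param model a [structure_model()] containing hydrogens.
#' @param donor_sel,acceptor_sel selection expressions.
#' @param criteria an [hbond_criteria()].
#' @return integer hydrogen-bond count.
#' @export
hbond_count <- function(frame, model, donor_sel, acceptor_sel,
                        criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  a <- model$atoms
  id <- resolve_selection(model, donor_sel)
  iacc <- resolve_selection(model, acceptor_sel)
  id <- id[!a$is_hydrogen[id] & a$element[id] %in% c("N", "O")]
  iacc <- iacc[!a$is_hydrogen[iacc] & a$element[iacc] %in% c("N", "O")]
  ih <- which(a$is_hydrogen)
  if (length(id) == 0 || length(iacc) == 0 || length(ih) == 0) return(0L)

  # attach hydrogens to donors (<= 1.2 A)
  dh <- .pairs_within(frame[id, , drop = FALSE], frame[ih, , drop = FALSE],
                      1.2, inclusive = TRUE)
  if (nrow(dh) == 0) return(0L)
  count <- 0L
  da <- .pairs_within(frame[id, , drop = FALSE], frame[iacc, , drop = FALSE],
                      criteria$da_cutoff, inclusive = TRUE)
  if (nrow(da) == 0) return(0L)
  # drop donor==acceptor self pairs
  da <- da[id[da$i] != iacc[da$j], , drop = FALSE]
  for (k in seq_len(nrow(da))) {
    dglob <- id[da$i[k]]
    aglob <- iacc[da$j[k]]
    hs <- ih[dh$j[dh$i == da$i[k]]]
    for (h in hs) {
      v1 <- frame[dglob, ] - frame[h, ]
      v2 <- frame[aglob, ] - frame[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= criteria$angle_min - 1e-9) count <- count + 1L
    }
  }
  count
}

#' Per-frame interface metric as an ensemble series
#'
#' Evaluates a contact or hydrogen-bond count for every frame of every
#' replica of a (balanced) ensemble and aggregates with [ensemble_stats()].
#'
#' @param ensemble a [replica_ensemble()], typically from
#'   [balanced_frames()].
#' @param metric `"contacts"` or `"hbonds"`.
#' @param sel_a,sel_b the two groups: antigen/binder selections for
#'   contacts, donor/acceptor selections for hydrogen bonds.
#' @param cutoff contact cutoff, Angstrom (contacts only), default 4.5.
#' @param criteria an [hbond_criteria()] (hbonds only).
#' @return an `ensemble_series` (see [ensemble_stats()]).
#' @export
interface_series <- function(ensemble, metric = c("contacts", "hbonds"),
                             sel_a, sel_b, cutoff = 4.5,
                             criteria = hbond_criteria()) {
  stopifnot(inherits(ensemble, "replica_ensemble"))
  metric <- match.arg(metric)
  series <- lapply(ensemble$replicas, function(tr) {
    vals <- vapply(seq_len(n_frames(tr)), function(i) {
      f <- frame_coords(tr, i)
      if (metric == "contacts") {
        as.numeric(contact_count(f, tr$topology, sel_a, sel_b,
                                 cutoff = cutoff))
      } else {
        as.numeric(hbond_count(f, tr$topology, sel_a, sel_b,
                               criteria = criteria))
      }
    }, numeric(1))
    time_series(tr$frame_times, vals, label = metric)
  })
  ensemble_stats(series)
}

#' Percent difference between two ensemble means
#'
#' `100 * (mean(a) - mean(b)) / mean(b)`, where each ensemble mean is the
#' equal-weight mean over replicas of the per-replica time average (replica
#' means are averaged, not pooled frames).
#'
#' @param a,b `ensemble_series` objects (see [ensemble_stats()]).
#' @return percent difference (positive when `a` exceeds `b`).
#' @export
percent_difference <- function(a, b) {
  stopifnot(inherits(a, "ensemble_series"), inherits(b, "ensemble_series"))
  ma <- mean(colMeans(a$values))
  mb <- mean(colMeans(b$values))
  if (mb == 0) stop("undefined ratio: reference ensemble mean is zero")
  100 * (ma - mb) / mb
}
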