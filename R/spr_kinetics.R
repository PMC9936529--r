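# Bivalent-analyte and heterogeneous two-site SPR kinetics: sensorgram
# simulation, global least-squares fitting and equilibrium-constant
# derivation.
#
# Two model variants are provided because published two-capacity parameter
# tables (Bmax1 and Bmax2) are ambiguous about the underlying scheme:
#  * "bivalent": a first binding event (ka1, kd1) can be followed by a
#    second attachment of the already-bound analyte (ka2, kd2) consuming
#    further surface sites; one total capacity Bmax (= Bmax1), ka2 in
#    RU^-1 s^-1.
#  * "two_site": two independent parallel Langmuir sites with capacities
#    Bmax1 and Bmax2, both ka in M^-1 s^-1 -- the interpretation consistent
#    with a parameter table listing two capacities.

#' Kinetic parameters for surface binding models
#'
#' @param ka1 association rate of the first step, 1/(M s).
#' @param kd1 dissociation rate of the first step, 1/s.
#' @param ka2 association rate of the second step; units depend on the
#'   model: 1/(RU s) for `"bivalent"` (the second step consumes surface
#'   sites), 1/(M s) for `"two_site"`.
#' @param kd2 dissociation rate of the second step, 1/s.
#' @param Bmax1 surface capacity, RU (the only capacity used by the
#'   bivalent model).
#' @param Bmax2 capacity of the second site, RU (two-site model only).
#' @return object of class `bivalent_params`.
#' @export
bivalent_params <- function(ka1, kd1, ka2, kd2, Bmax1, Bmax2 = 0) {
  vals <- c(ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2, Bmax1 = Bmax1)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("rates and Bmax1 must be positive and finite")
  }
  if (!is.finite(Bmax2) || Bmax2 < 0) stop("Bmax2 must be >= 0")
  structure(list(ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2,
                 Bmax1 = Bmax1, Bmax2 = Bmax2),
            class = "bivalent_params")
}

#' @export
print.bivalent_params <- function(x, ...) {
  cat("binding kinetics parameters:\n")
  cat(sprintf("  ka1 = %.4g 1/(M s)   kd1 = %.4g 1/s   KD1 = %.4g M\n",
              x$ka1, x$kd1, derive_kd(x$ka1, x$kd1)))
  cat(sprintf("  ka2 = %.4g           kd2 = %.4g 1/s   KD2 = %.4g\n",
              x$ka2, x$kd2, derive_kd(x$ka2, x$kd2)))
  cat(sprintf("  Bmax1 = %.4g RU  Bmax2 = %.4g RU\n", x$Bmax1, x$Bmax2))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `KD = kd / ka`, units propagated from the inputs (M for a step with ka
#' in 1/(M s)).
#'
#' @param ka association rate constant (> 0).
#' @param kd dissociation rate constant.
#' @return the exact quotient `kd / ka`.
#' @export
derive_kd <- function(ka, kd) {
  if (!is.numeric(ka) || any(ka <= 0)) stop("ka must be positive")
  kd / ka
}

#' Check a reported KD against its rate constants
#'
#' Recomputes `KD = kd/ka` and compares it with a reported value at
#' `sig` significant figures, allowing one unit in the last figure (printed
#' inputs are themselves rounded). Useful for validating published kinetic
#' tables row by row.
#'
#' @param ka,kd rate constants.
#' @param kd_reported the KD value as printed.
#' @param sig significant figures of the printed value, default 3.
#' @return list with `implied` (the recomputed KD), `reported`,
#'   `consistent` (logical) and `ratio` (implied / reported).
#' @export
validate_kd <- function(ka, kd, kd_reported, sig = 3) {
  implied <- derive_kd(ka, kd)
  ulp <- 10^(floor(log10(abs(kd_reported))) - (sig - 1))
  consistent <- abs(signif(implied, sig) - kd_reported) <= ulp * (1 + 1e-9)
  list(implied = implied, reported = kd_reported,
       consistent = consistent, ratio = implied / kd_reported)
}

#' Published SPR kinetic constants for the two anti-PD-L1 clones
#'
#' Loads the bivalent-fit rate constants, capacities and reported
#' equilibrium constants for monoclonal antibody clones 11B12-1 and 12F1-1
#' binding hamster PD-L1, shipped with the package as a plain-text table.
#'
#' @return data.frame with one row per clone and columns `clone`, `Bmax1`,
#'   `ka1`, `kd1`, `KD1_reported`, `Bmax2`, `ka2`, `kd2`, `KD2_reported`.
#' @export
reference_kinetics <- function() {
  path <- system.file("extdata", "anti_pdl1_spr_constants.csv",
                      package = "epibind")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.integrate_phase <- function(y0, times, parms, func, init, rtol, atol) {
  if (length(times) == 1) {
    return(matrix(c(times, y0), nrow = 1,
                  dimnames = list(NULL, c("time", "R1", "R2"))))
  }
  out <- deSolve::ode(y = c(R1 = y0[1], R2 = y0[2]), times = times,
                      func = func, parms = parms, dllname = "epibind",
                      initfunc = init, rtol = rtol, atol = atol,
                      method = "lsoda")
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         "); parameters: ", paste(signif(parms, 4), collapse = ", "))
  }
  colnames(out) <- c("time", "R1", "R2")
  out
}

.simulate_core <- function(params, conc, times, t_assoc_end, model,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "bivalent_params"), conc >= 0)
  times <- sort(unique(as.numeric(times)))
  pa <- if (model == "bivalent") {
    c(params$ka1, params$kd1, params$ka2, params$kd2, params$Bmax1, conc)
  } else {
    c(params$ka1, params$kd1, params$ka2, params$kd2,
      params$Bmax1, params$Bmax2, conc)
  }
  func <- if (model == "bivalent") "derivs_bivalent" else "derivs_two_site"
  init <- if (model == "bivalent") "init_bivalent" else "init_two_site"

  t_a <- times[times <= t_assoc_end + 1e-12]
  t_d <- times[times > t_assoc_end + 1e-12]
  grid_a <- sort(unique(c(0, t_a, t_assoc_end)))
  out_a <- .integrate_phase(c(0, 0), grid_a, pa, func, init, rtol, atol)
  y_end <- out_a[nrow(out_a), c("R1", "R2")]
  comp <- out_a[match(t_a, out_a[, "time"]), c("R1", "R2"), drop = FALSE]
  phase <- rep("association", length(t_a))
  if (length(t_d) > 0) {
    pd <- pa
    pd[length(pd)] <- 0  # analyte washed out
    grid_d <- sort(unique(c(t_assoc_end, t_d)))
    out_d <- .integrate_phase(as.numeric(y_end), grid_d, pd, func, init,
                              rtol, atol)
    comp <- rbind(comp,
                  out_d[match(t_d, out_d[, "time"]), c("R1", "R2"),
                        drop = FALSE])
    phase <- c(phase, rep("dissociation", length(t_d)))
  }
  sg <- data.frame(time = c(t_a, t_d),
                   response = comp[, "R1"] + comp[, "R2"],
                   conc = conc, phase = phase)
  attr(sg, "components") <- comp
  attr(sg, "t_assoc_end") <- t_assoc_end
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' Simulate a sensorgram under the bivalent-analyte model
#'
#' Integrates
#' \deqn{dR_1/dt = k_{a1} C (B_{max} - R_1 - R_2) - k_{d1} R_1
#'       - k_{a2} R_1 (B_{max} - R_1 - R_2) + k_{d2} R_2}
#' \deqn{dR_2/dt = k_{a2} R_1 (B_{max} - R_1 - R_2) - k_{d2} R_2}
#' with the analyte concentration `C = conc` during association and `C = 0`
#' during dissociation, starting from a bare surface. The response is
#' `R1 + R2`. Integration uses `lsoda` (stiff-safe) with relative tolerance
#' 1e-8 and absolute tolerance 1e-10 RU.
#'
#' @param params a [bivalent_params()] (`Bmax1` is the surface capacity;
#'   `Bmax2` is ignored by this variant).
#' @param conc analyte concentration in M during association.
#' @param times output times in seconds (both phases).
#' @param t_assoc_end end of the association phase, seconds.
#' @param rtol,atol solver tolerances.
#' @return object of class `sensorgram`: data.frame with `time`,
#'   `response` (RU), `conc`, `phase`; the per-state components are kept in
#'   the `"components"` attribute.
#' @export
simulate_bivalent <- function(params, conc, times, t_assoc_end,
                              rtol = 1e-8, atol = 1e-10) {
  .simulate_core(params, conc, times, t_assoc_end, "bivalent", rtol, atol)
}

#' Simulate a sensorgram under the heterogeneous two-site model
#'
#' Two independent parallel Langmuir sites with capacities `Bmax1` and
#' `Bmax2`; `R = R_site1 + R_site2`, each site following
#' `dR_i/dt = ka_i C (Bmax_i - R_i) - kd_i R_i`.
#'
#' @inheritParams simulate_bivalent
#' @return a `sensorgram` (see [simulate_bivalent()]).
#' @export
simulate_two_site <- function(params, conc, times, t_assoc_end,
                              rtol = 1e-8, atol = 1e-10) {
  .simulate_core(params, conc, times, t_assoc_end, "two_site", rtol, atol)
}

#' Read / write a sensorgram CSV
#'
#' Column layout: `time_s`, `response_RU`, `conc_M`, `phase`
#' (`association` or `dissociation`).
#'
#' @param path CSV path.
#' @return [read_sensorgram()]: a `sensorgram` data.frame.
#' @export
read_sensorgram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  if (!all(need %in% names(d))) {
    stop("sensorgram CSV must have columns ", paste(need, collapse = ", "))
  }
  sg <- data.frame(time = d$time_s, response = d$response_RU,
                   conc = d$conc_M, phase = d$phase)
  ta <- sg$time[sg$phase == "association"]
  attr(sg, "t_assoc_end") <- if (length(ta) > 0) max(ta) else 0
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' @rdname read_sensorgram
#' @param sg a `sensorgram`.
#' @export
write_sensorgram <- function(sg, path) {
  utils::write.csv(data.frame(time_s = sg$time, response_RU = sg$response,
                              conc_M = sg$conc, phase = sg$phase),
                   path, row.names = FALSE)
  invisible(path)
}

.par_names <- function(model) {
  if (model == "bivalent") c("ka1", "kd1", "ka2", "kd2", "Bmax1")
  else c("ka1", "kd1", "ka2", "kd2", "Bmax1", "Bmax2")
}

.default_box <- function(model) {
  if (model == "bivalent") {
    list(lower = c(ka1 = 1e2, kd1 = 1e-6, ka2 = 1e-7, kd2 = 1e-6,
                   Bmax1 = 1e-2),
         upper = c(ka1 = 1e8, kd1 = 1e0, ka2 = 1e0, kd2 = 1e0,
                   Bmax1 = 1e4))
  } else {
    list(lower = c(ka1 = 1e2, kd1 = 1e-6, ka2 = 1e2, kd2 = 1e-6,
                   Bmax1 = 1e-2, Bmax2 = 1e-2),
         upper = c(ka1 = 1e8, kd1 = 1e0, ka2 = 1e8, kd2 = 1e0,
                   Bmax1 = 1e4, Bmax2 = 1e4))
  }
}

.params_from_vec <- function(p, model) {
  if (model == "bivalent") {
    bivalent_params(p["ka1"], p["kd1"], p["ka2"], p["kd2"], p["Bmax1"])
  } else {
    bivalent_params(p["ka1"], p["kd1"], p["ka2"], p["kd2"], p["Bmax1"],
                    p["Bmax2"])
  }
}

# residuals over all curves for a natural-scale parameter vector
.spr_residuals <- function(p, sensorgrams, model, rtol, atol) {
  params <- .params_from_vec(p, model)
  unlist(lapply(sensorgrams, function(sg) {
    sim <- .simulate_core(params, sg$conc[1], sg$time,
                          attr(sg, "t_assoc_end"), model,
                          rtol = rtol, atol = atol)
    sg$response - sim$response
  }), use.names = FALSE)
}

# data-driven heuristic starting point
.heuristic_start <- function(sensorgrams, model, box) {
  rmax <- max(vapply(sensorgrams, function(s) max(s$response), numeric(1)))
  bmax0 <- max(1.2 * rmax, box$lower["Bmax1"] * 2)
  kd0 <- 1e-3
  sg <- sensorgrams[[which.max(vapply(sensorgrams,
                                      function(s) s$conc[1], numeric(1)))]]
  dis <- sg[sg$phase == "dissociation" & sg$response > 0, ]
  if (nrow(dis) > 5) {
    sl <- stats::coef(stats::lm(log(response) ~ time, data = dis))[2]
    if (is.finite(sl) && sl < 0) kd0 <- min(max(-sl, 1e-5), 0.5)
  }
  p <- c(ka1 = 1e5, kd1 = unname(kd0),
         ka2 = if (model == "bivalent") 1e-3 else 1e4,
         kd2 = 1e-3, Bmax1 = unname(bmax0))
  if (model == "two_site") p <- c(p, Bmax2 = unname(bmax0) / 3)
  pmin(pmax(p, box$lower * 1.01), box$upper * 0.99)
}

#' Globally fit SPR sensorgrams to a surface-binding kinetic model
#'
#' Fits one shared parameter set to all supplied sensorgrams (all analyte
#' concentrations simultaneously) by trust-region least squares on
#' log10-transformed parameters, with a multi-start strategy: one
#' data-driven heuristic start plus seeded log-uniform random starts inside
#' the parameter box. The best converged start by residual sum of squares
#' is returned. Deterministic for a fixed `seed`.
#'
#' @param sensorgrams list of `sensorgram` objects (one per analyte
#'   concentration; a single curve triggers a warning since rate and
#'   capacity are then poorly separable).
#' @param model `"bivalent"` (default) or `"two_site"`.
#' @param n_starts number of optimisation starts, default 8.
#' @param seed integer seed for the random starts.
#' @param lower,upper named parameter boxes (natural scale); defaults span
#'   typical antibody-antigen kinetics.
#' @param start optional named vector overriding the heuristic start.
#' @param rtol,atol ODE solver tolerances used inside the objective.
#' @param ftol,ptol optimiser convergence tolerances (default 1e-10).
#' @param maxit maximum optimiser iterations per start.
#' @return object of class `spr_fit` with components `params`
#'   (a [bivalent_params()]), `coefficients`, `se` (delta-method standard
#'   errors), `rss`, `converged`, `degenerate`, `model`, `ka2_units`,
#'   `data`, `n_obs`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `plot`.
#' @export
fit_spr <- function(sensorgrams, model = c("bivalent", "two_site"),
                    n_starts = 8, seed = 1, lower = NULL, upper = NULL,
                    start = NULL, rtol = 1e-6, atol = 1e-8,
                    ftol = 1e-10, ptol = 1e-10, maxit = 150) {
  model <- match.arg(model)
  stopifnot(is.list(sensorgrams), length(sensorgrams) >= 1)
  if (length(sensorgrams) < 2) {
    warning("global fitting with a single concentration is ",
            "poorly constrained")
  }
  box <- .default_box(model)
  if (!is.null(lower)) box$lower[names(lower)] <- lower
  if (!is.null(upper)) box$upper[names(upper)] <- upper
  pn <- .par_names(model)

  resp_all <- unlist(lapply(sensorgrams, function(s) s$response))
  n_obs <- length(resp_all)
  degenerate <- all(abs(resp_all) < 1e-12)
  if (degenerate) {
    p <- box$lower
    params <- .params_from_vec(p, model)
    return(structure(list(params = params, coefficients = p,
                          se = stats::setNames(rep(NA_real_, length(p)), pn),
                          rss = sum(resp_all^2), converged = FALSE,
                          degenerate = TRUE, model = model,
                          ka2_units = if (model == "bivalent") "1/(RU s)"
                                      else "1/(M s)",
                          data = sensorgrams, n_obs = n_obs,
                          n_starts = 0, seed = seed),
                     class = "spr_fit"))
  }

  obj_log <- function(lp) {
    p <- stats::setNames(10^lp, pn)
    tryCatch(.spr_residuals(p, sensorgrams, model, rtol, atol),
             error = function(e) rep(1e6, n_obs))
  }

  ## candidate starting points -------------------------------------------
  # (1) data-driven heuristic; (2) a single-site prefit of (ka1, kd1,
  # Bmax1) with the second step frozen near zero -- the well-behaved
  # sub-problem that usually lands in the right basin; (3) seeded
  # log-uniform points. All candidates are screened by one objective
  # evaluation and the optimiser is run only from the best `n_starts`.
  cands <- list(if (is.null(start))
                  .heuristic_start(sensorgrams, model, box)
                else pmin(pmax(start[pn], box$lower), box$upper))

  prefit_start <- tryCatch({
    h <- cands[[1]]
    pn3 <- c("ka1", "kd1", "Bmax1")
    fill <- function(p3) {
      p <- stats::setNames(numeric(length(pn)), pn)
      p[pn3] <- p3
      p["ka2"] <- box$lower["ka2"]
      p["kd2"] <- box$upper["kd2"]   # second state empties instantly
      if (model == "two_site") p["Bmax2"] <- box$lower["Bmax2"]
      p
    }
    obj3 <- function(lp3) {
      p <- fill(stats::setNames(10^lp3, pn3))
      tryCatch(.spr_residuals(p, sensorgrams, model, rtol, atol),
               error = function(e) rep(1e6, n_obs))
    }
    f3 <- minpack.lm::nls.lm(par = log10(h[pn3]), fn = obj3,
                             lower = log10(box$lower[pn3]),
                             upper = log10(box$upper[pn3]),
                             control = minpack.lm::nls.lm.control(
                               ftol = 1e-8, ptol = 1e-8, maxiter = 80))
    stats::setNames(10^stats::coef(f3), pn3)
  }, error = function(e) NULL)
  if (!is.null(prefit_start)) {
    # seed the second step at several magnitudes around the prefit
    for (f2 in c(1e-3, 1e-2, 1e-1)) {
      p <- stats::setNames(numeric(length(pn)), pn)
      p[c("ka1", "kd1", "Bmax1")] <- prefit_start
      p["ka2"] <- sqrt(box$lower["ka2"] * box$upper["ka2"]) * f2 / 1e-2
      p["kd2"] <- f2 * prefit_start["kd1"] / 1e-2
      if (model == "two_site") p["Bmax2"] <- prefit_start["Bmax1"] / 3
      cands[[length(cands) + 1]] <-
        pmin(pmax(p, box$lower), box$upper)
    }
  }
  n_random <- max(4 * n_starts, 32)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (k in seq_len(n_random)) {
    u <- stats::runif(length(pn))
    cands[[length(cands) + 1]] <- stats::setNames(
      10^(log10(box$lower) + u * (log10(box$upper) - log10(box$lower))),
      pn)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  screen <- vapply(cands, function(p) sum(obj_log(log10(p))^2), numeric(1))
  starts <- cands[order(screen)][seq_len(min(n_starts, length(cands)))]

  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = log10(s0), fn = obj_log,
                         lower = log10(box$lower), upper = log10(box$upper),
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = ptol, maxiter = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = res, rss = rss)
    }
  }

  if (is.null(best)) {
    p <- starts[[1]]
    return(structure(list(params = .params_from_vec(p, model),
                          coefficients = p,
                          se = stats::setNames(rep(NA_real_, length(p)), pn),
                          rss = NA_real_, converged = FALSE,
                          degenerate = FALSE, model = model,
                          ka2_units = if (model == "bivalent") "1/(RU s)"
                                      else "1/(M s)",
                          data = sensorgrams, n_obs = n_obs,
                          n_starts = n_starts, seed = seed),
                     class = "spr_fit"))
  }

  # polish the best start at tighter ODE tolerance so the optimum is not
  # limited by integration error
  obj_fine <- function(lp) {
    p <- stats::setNames(10^lp, pn)
    tryCatch(.spr_residuals(p, sensorgrams, model,
                            rtol = min(rtol, 1e-8), atol = min(atol, 1e-10)),
             error = function(e) rep(1e6, n_obs))
  }
  pol <- tryCatch(
    minpack.lm::nls.lm(par = stats::coef(best$fit), fn = obj_fine,
                       lower = log10(box$lower), upper = log10(box$upper),
                       control = minpack.lm::nls.lm.control(
                         ftol = ftol, ptol = ptol, maxiter = maxit)),
    error = function(e) NULL)
  if (!is.null(pol) && sum(pol$fvec^2) <= best$rss) {
    best <- list(fit = pol, rss = sum(pol$fvec^2))
  }

  fit <- best$fit
  p <- stats::setNames(10^stats::coef(fit), pn)
  se <- tryCatch({
    np <- length(pn)
    cov_log <- best$rss / max(n_obs - np, 1) * solve(fit$hessian)
    sqrt(pmax(diag(cov_log), 0)) * log(10) * p   # delta method to natural
  }, error = function(e) stats::setNames(rep(NA_real_, length(pn)), pn))
  structure(list(params = .params_from_vec(p, model), coefficients = p,
                 se = stats::setNames(as.numeric(se), pn), rss = best$rss,
                 converged = fit$info %in% 1:4, degenerate = FALSE,
                 model = model,
                 ka2_units = if (model == "bivalent") "1/(RU s)"
                             else "1/(M s)",
                 data = sensorgrams, n_obs = n_obs, n_starts = n_starts,
                 seed = seed),
            class = "spr_fit")
}

#' @export
coef.spr_fit <- function(object, ...) object$coefficients

#' @export
print.spr_fit <- function(x, ...) {
  cat("Global SPR kinetic fit (", x$model, " model)\n", sep = "")
  cat("  curves: ", length(x$data), "  observations: ", x$n_obs,
      "  RSS: ", format(x$rss, digits = 6), " RU^2\n", sep = "")
  cat("  converged: ", x$converged,
      if (x$degenerate) "  [degenerate input]" else "", "\n", sep = "")
  print(x$params)
  cat("  (ka2 units: ", x$ka2_units, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.spr_fit <- function(object, ...) {
  p <- object$coefficients
  kd1 <- derive_kd(p["ka1"], p["kd1"])
  kd2 <- derive_kd(p["ka2"], p["kd2"])
  out <- list(
    model = object$model,
    table = data.frame(estimate = p, std_error = object$se),
    KD1 = unname(kd1), KD2 = unname(kd2),
    ka2_units = object$ka2_units,
    rss = object$rss, n_obs = object$n_obs,
    converged = object$converged, degenerate = object$degenerate)
  class(out) <- "summary.spr_fit"
  out
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  cat("Global SPR kinetic fit (", x$model, " model)\n", sep = "")
  print(signif(x$table, 4))
  cat(sprintf("KD1 = kd1/ka1 = %.4g M\nKD2 = kd2/ka2 = %.4g (ka2 %s)\n",
              x$KD1, x$KD2, x$ka2_units))
  cat(sprintf("RSS %.6g RU^2 over %d observations; converged: %s\n",
              x$rss, x$n_obs, x$converged))
  invisible(x)
}

#' @export
fitted.spr_fit <- function(object, ...) {
  lapply(object$data, function(sg) {
    .simulate_core(object$params, sg$conc[1], sg$time,
                   attr(sg, "t_assoc_end"), object$model)$response
  })
}

#' @export
residuals.spr_fit <- function(object, ...) {
  f <- fitted(object)
  Map(function(sg, fv) sg$response - fv, object$data, f)
}

#' Predict a sensorgram from a fitted SPR model
#'
#' @param object an `spr_fit`.
#' @param conc analyte concentration, M. If missing, fitted curves for the
#'   training data are returned.
#' @param times output times, seconds.
#' @param t_assoc_end association end, seconds.
#' @param ... ignored.
#' @return a `sensorgram`, or the list of fitted response vectors when
#'   `conc` is missing.
#' @export
predict.spr_fit <- function(object, conc, times, t_assoc_end, ...) {
  if (missing(conc)) return(fitted(object))
  .simulate_core(object$params, conc, times, t_assoc_end, object$model)
}

#' Simulate noisy sensorgrams from a fitted SPR model
#'
#' @param object an `spr_fit`.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param noise_frac Gaussian noise standard deviation as a fraction of
#'   Bmax1, default 0.01.
#' @param ... ignored.
#' @return list of `nsim` lists of `sensorgram` objects matching the
#'   training design.
#' @export
simulate.spr_fit <- function(object, nsim = 1, seed = NULL,
                             noise_frac = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  sdev <- noise_frac * object$params$Bmax1
  lapply(seq_len(nsim), function(k) {
    Map(function(sg, fv) {
      sg$response <- fv + stats::rnorm(length(fv), 0, sdev)
      sg
    }, object$data, f)
  })
}

#' Plot a fitted SPR model over its data
#'
#' @param x an `spr_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spr_fit <- function(x, ...) {
  f <- fitted(x)
  rng_t <- range(unlist(lapply(x$data, function(s) s$time)))
  rng_r <- range(c(unlist(lapply(x$data, function(s) s$response)),
                   unlist(f)))
  graphics::plot(NA, xlim = rng_t, ylim = rng_r, xlab = "time (s)",
                 ylab = "response (RU)",
                 main = paste("SPR global fit:", x$model), ...)
  for (i in seq_along(x$data)) {
    graphics::points(x$data[[i]]$time, x$data[[i]]$response, pch = 16,
                     cex = 0.3, col = grDevices::grey(0.6))
    graphics::lines(x$data[[i]]$time, f[[i]], col = i + 1, lwd = 2)
  }
  invisible(x)
}
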