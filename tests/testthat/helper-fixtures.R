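# Shared fixtures and independent brute-force oracles for the test suite.
# The oracles are deliberately written as plain loops, independent of the
# package's vectorised implementations.

# Build a structure_model from a compact atom spec: data.frame with
# chain, resid, name, element, x, y, z (one row per atom).
toy_model <- function(df, model_id = "toy") {
  structure_model(data.frame(
    serial = seq_len(nrow(df)),
    name = df$name,
    element = df$element,
    x = df$x, y = df$y, z = df$z,
    chain_id = df$chain,
    residue_index = df$resid,
    ins = "",
    residue_name = "ALA",
    occupancy = 1.0,
    bfactor = if (is.null(df$bfactor)) 0 else df$bfactor,
    stringsAsFactors = FALSE), model_id = model_id)
}

# One-frame trajectory from a model plus a list of coordinate matrices.
toy_traj <- function(model, frame_list, times = NULL) {
  trajectory(model, frame_list, frame_times = times)
}

# O(N*M) loop enumeration of cross-group atom pairs within a cutoff.
brute_pairs <- function(A, B, cutoff, inclusive = FALSE) {
  hits <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      ok <- if (inclusive) d <= cutoff else d < cutoff
      if (ok) hits[[length(hits) + 1]] <- c(i, j, d)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
}

# Triple-loop hydrogen-bond enumeration: donors are N/O heavy atoms of the
# donor index set with a hydrogen within 1.2 A, acceptors N/O heavy atoms.
brute_hbonds <- function(frame, model, donor_idx, acceptor_idx,
                         da_cutoff = 3.5, angle_min = 150) {
  a <- model$atoms
  donor_idx <- donor_idx[!a$is_hydrogen[donor_idx] &
                         a$element[donor_idx] %in% c("N", "O")]
  acceptor_idx <- acceptor_idx[!a$is_hydrogen[acceptor_idx] &
                               a$element[acceptor_idx] %in% c("N", "O")]
  h_idx <- which(a$is_hydrogen)
  n <- 0L
  for (d in donor_idx) {
    for (h in h_idx) {
      if (sqrt(sum((frame[d, ] - frame[h, ])^2)) > 1.2) next
      for (acc in acceptor_idx) {
        if (acc == d) next
        if (sqrt(sum((frame[d, ] - frame[acc, ])^2)) > da_cutoff) next
        v1 <- frame[d, ] - frame[h, ]
        v2 <- frame[acc, ] - frame[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= angle_min) n <- n + 1L
      }
    }
  }
  n
}

# Numerical superposition oracle: minimise RMSD over Euler angles plus
# translation with a general-purpose optimiser (independent of the SVD
# solution path).
numeric_superpose_rmsd <- function(mobile, reference) {
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rotmat(par[1:3])
    moved <- sweep(mobile %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  set.seed(42)
  for (k in 1:12) {
    p0 <- c(stats::runif(3, -pi, pi),
            colMeans(reference) - colMeans(mobile))
    o <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Random heavy-atom point clouds for property tests.
random_cloud_model <- function(n, seed, spread = 12) {
  set.seed(seed)
  half <- n %/% 2
  toy_model(data.frame(
    chain = rep(c("A", "B"), c(half, n - half)),
    resid = seq_len(n),
    name = "CA",
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    x = stats::runif(n, 0, spread),
    y = stats::runif(n, 0, spread),
    z = stats::runif(n, 0, spread)))
}
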