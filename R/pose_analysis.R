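# Rigid-body superposition, interface epitope mapping, steric-clash scanning
# and competition assessment between binding poses.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atoms of a mobile and a reference coordinate set. Coordinates are
#' row vectors; the fitted position of a point `p` is
#' `p %*% rotation + translation`.
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param fit_mobile,fit_reference paired index vectors of equal length
#'   (default: all rows) selecting the atoms used for the fit.
#' @return object of class `rigid_transform`: list with `rotation` (3x3,
#'   determinant +1), `translation` (length 3) and `fit_rmsd` (Angstrom,
#'   over the fit atoms after transformation).
#' @export
kabsch_superpose <- function(mobile, reference,
                             fit_mobile = seq_len(nrow(mobile)),
                             fit_reference = seq_len(nrow(reference))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (length(fit_mobile) != length(fit_reference)) {
    stop("paired fit index lists must have equal length")
  }
  if (length(fit_mobile) < 3) {
    stop("degenerate fit: at least 3 paired atoms are required")
  }
  A <- mobile[fit_mobile, , drop = FALSE]
  B <- reference[fit_reference, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_check <- svd(Ac)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1e-12)) {
    stop("degenerate fit: fit atoms are collinear")
  }
  H <- crossprod(Ac, Bc)              # t(Ac) %*% Bc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- as.numeric(cb - ca %*% R)
  fitted <- sweep(A %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, fit_rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: fit RMSD", format(x$fit_rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz `n x 3` coordinate matrix.
#' @param transform a `rigid_transform` from [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(xyz) %*% transform$rotation, 2, transform$translation, "+")
}

# All pairs (i in A, j in B) with distance strictly below `cutoff`
# (or at most `cutoff` when inclusive = TRUE). Vectorised O(N*M) scan in
# column blocks to bound memory; correctness is pinned against brute-force
# enumeration in the test suite.
.pairs_within <- function(A, B, cutoff, inclusive = FALSE,
                          block = 2048L) {
  A <- as.matrix(A); B <- as.matrix(B)
  ra <- rowSums(A^2)
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  c2 <- cutoff^2
  for (start in seq(1L, nrow(B), by = block)) {
    jj <- start:min(start + block - 1L, nrow(B))
    Bb <- B[jj, , drop = FALSE]
    d2 <- outer(ra, rowSums(Bb^2), "+") - 2 * tcrossprod(A, Bb)
    hit <- if (inclusive) which(d2 <= c2 + 1e-12, arr.ind = TRUE)
           else which(d2 < c2 - 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out_i <- c(out_i, hit[, 1])
      out_j <- c(out_j, jj[hit[, 2]])
      out_d <- c(out_d, sqrt(pmax(d2[hit], 0)))
    }
  }
  ord <- order(out_i, out_j)
  data.frame(i = out_i[ord], j = out_j[ord], distance = out_d[ord])
}

#' Scan for steric clashes between two atom selections
#'
#' Reports every heavy-atom pair across the two selections closer than the
#' cutoff (strictly; default 3.0 Angstrom, i.e. 0.3 nm). Both structures
#' must already be in a common frame; superpose first if needed.
#'
#' @param model_a,model_b [structure_model()] objects (may be the same
#'   model).
#' @param sel_a,sel_b selection expressions (see [resolve_selection()]);
#'   hydrogens are excluded automatically.
#' @param cutoff clash distance in Angstrom, default 3.0.
#' @return object of class `clash_report`: list with `cutoff`, `pairs`
#'   (data.frame `atom_a`, `atom_b` indices into the respective models,
#'   `distance`), and `clash_residues` (data.frame of `side`, `chain_id`,
#'   `residue_key` for every residue involved).
#' @export
steric_clash_scan <- function(model_a, sel_a, model_b, sel_b, cutoff = 3.0) {
  ia <- resolve_selection(model_a, sel_a)
  ib <- resolve_selection(model_b, sel_b)
  ia <- ia[!model_a$atoms$is_hydrogen[ia]]
  ib <- ib[!model_b$atoms$is_hydrogen[ib]]
  if (length(ia) == 0 || length(ib) == 0) {
    stop("empty selection in clash scan")
  }
  .clash_from_coords(coords(model_a)[ia, , drop = FALSE],
                     coords(model_b)[ib, , drop = FALSE],
                     model_a, model_b, ia, ib, cutoff)
}

.clash_from_coords <- function(A, B, model_a, model_b, ia, ib, cutoff) {
  p <- .pairs_within(A, B, cutoff, inclusive = FALSE)
  pairs <- data.frame(atom_a = ia[p$i], atom_b = ib[p$j],
                      distance = p$distance)
  res <- rbind(
    if (nrow(pairs) > 0)
      unique(data.frame(side = "A",
                        chain_id = model_a$atoms$chain_id[pairs$atom_a],
                        residue_key = model_a$atoms$residue_key[pairs$atom_a]))
    else NULL,
    if (nrow(pairs) > 0)
      unique(data.frame(side = "B",
                        chain_id = model_b$atoms$chain_id[pairs$atom_b],
                        residue_key = model_b$atoms$residue_key[pairs$atom_b]))
    else NULL)
  if (is.null(res)) {
    res <- data.frame(side = character(0), chain_id = character(0),
                      residue_key = character(0))
  }
  rownames(res) <- NULL
  structure(list(cutoff = cutoff, pairs = pairs, clash_residues = res),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("clash_report: ", nrow(x$pairs), " heavy-atom pair(s) < ",
      x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Map the epitope of a bound pose by interface contacts
#'
#' Identifies the antigen residues having at least one heavy-atom pair
#' within the contact cutoff (strictly closer than; default 4.5 Angstrom)
#' of the binder selection, with per-residue pair counts.
#'
#' @param complex a [structure_model()] containing both antigen and binder.
#' @param antigen_sel,binder_sel disjoint selection expressions.
#' @param cutoff contact distance in Angstrom, default 4.5.
#' @return object of class `epitope_map`: data.frame with `chain_id`,
#'   `residue_key`, `residue_name`, `n_contacts`, ordered by file order.
#' @export
epitope_map <- function(complex, antigen_sel, binder_sel, cutoff = 4.5) {
  ia <- resolve_selection(complex, antigen_sel)
  ib <- resolve_selection(complex, binder_sel)
  if (length(intersect(ia, ib)) > 0) {
    stop("antigen and binder selections overlap")
  }
  ia <- ia[!complex$atoms$is_hydrogen[ia]]
  ib <- ib[!complex$atoms$is_hydrogen[ib]]
  xyz <- coords(complex)
  p <- .pairs_within(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                     cutoff, inclusive = FALSE)
  aidx <- ia[p$i]
  key <- paste(complex$atoms$chain_id[aidx], complex$atoms$residue_key[aidx],
               sep = "|")
  rt <- .residue_table(complex)
  counts <- table(factor(key, levels = rt$key))
  hit <- counts > 0
  out <- data.frame(chain_id = rt$chain_id[hit],
                    residue_key = rt$residue_key[hit],
                    residue_name = rt$residue_name[hit],
                    n_contacts = as.integer(counts[hit]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("epitope_map", "data.frame")
  out
}

#' Assess binding competition by superposition and clash scanning
#'
#' Superposes a reference complex (antigen + competitor, e.g. the natural
#' ligand or a second antigen copy) onto the antibody complex via the shared
#' antigen, then scans for steric clashes between the antibody and the
#' competitor. Any clash pair means the two binders cannot be accommodated
#' simultaneously, i.e. the antibody competes for the site.
#'
#' Antigen pairing uses CA atoms of residues common to both structures by
#' author numbering (the default, suited to structures of homologous
#' antigens numbered consistently), or an explicit pairing of atom indices
#' via `pairing`.
#'
#' @param antibody_complex [structure_model()] with the antibody bound to
#'   the antigen.
#' @param reference_complex [structure_model()] with the competitor bound to
#'   its copy of the antigen.
#' @param shared_antigen_sel selection resolving the shared antigen in both
#'   structures.
#' @param antibody_sel selection of the antibody in `antibody_complex`.
#' @param competitor_sel selection of the competitor in `reference_complex`.
#' @param clash_cutoff Angstrom, default 3.0.
#' @param pairing optional list with `antibody` and `reference` atom index
#'   vectors overriding the CA-by-common-numbering pairing.
#' @return list with `competes` (logical), `clash_report`, `fit_rmsd`
#'   (antigen superposition RMSD, Angstrom) and `transform`.
#' @export
competition_assessment <- function(antibody_complex, reference_complex,
                                   shared_antigen_sel, antibody_sel,
                                   competitor_sel, clash_cutoff = 3.0,
                                   pairing = NULL) {
  if (is.null(pairing)) {
    sel_ca <- paste(shared_antigen_sel, "and CA")
    ia <- resolve_selection(antibody_complex, sel_ca)
    ir <- resolve_selection(reference_complex, sel_ca)
    ka <- paste(antibody_complex$atoms$chain_id[ia],
                antibody_complex$atoms$residue_key[ia], sep = "|")
    kr <- paste(reference_complex$atoms$chain_id[ir],
                reference_complex$atoms$residue_key[ir], sep = "|")
    common <- intersect(ka, kr)
    if (length(common) < 3) {
      stop("antigen pairing failure: only ", length(common),
           " CA atoms shared by author numbering")
    }
    pairing <- list(antibody = ia[match(common, ka)],
                    reference = ir[match(common, kr)])
  }
  if (length(pairing$antibody) != length(pairing$reference)) {
    stop("antigen pairing failure: paired index lists differ in length")
  }
  tf <- kabsch_superpose(coords(reference_complex),
                         coords(antibody_complex),
                         fit_mobile = pairing$reference,
                         fit_reference = pairing$antibody)
  ref_xyz <- apply_transform(coords(reference_complex), tf)

  iab <- resolve_selection(antibody_complex, antibody_sel)
  icm <- resolve_selection(reference_complex, competitor_sel)
  iab <- iab[!antibody_complex$atoms$is_hydrogen[iab]]
  icm <- icm[!reference_complex$atoms$is_hydrogen[icm]]
  if (length(iab) == 0 || length(icm) == 0) {
    stop("empty antibody or competitor selection")
  }
  report <- .clash_from_coords(coords(antibody_complex)[iab, , drop = FALSE],
                               ref_xyz[icm, , drop = FALSE],
                               antibody_complex, reference_complex,
                               iab, icm, clash_cutoff)
  list(competes = nrow(report$pairs) > 0, clash_report = report,
       fit_rmsd = tf$fit_rmsd, transform = tf)
}
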