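# Post-processing of predicted complex models: confidence-based terminal
# trimming, pTM ranking, PAE summarisation and protocol bookkeeping.

#' Extract per-residue confidence (pLDDT) from a predicted model
#'
#' Predicted-model PDB files carry the per-residue pLDDT (0-100) in the
#' B-factor column, constant within a residue; the residue value is taken
#' from its first atom.
#'
#' @param model a [structure_model()].
#' @return named list, one numeric vector per chain in file order; values in
#'   \[0, 100\].
#' @export
plddt_profile <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  rt <- .residue_table(model)
  a <- model$atoms
  first <- !duplicated(paste(a$chain_id, a$residue_key, sep = "|"))
  vals <- a$bfactor[first]
  if (any(vals < 0 | vals > 100)) {
    stop("B-factor column does not look like pLDDT (values outside [0, 100])")
  }
  split(vals, factor(rt$chain_id, levels = unique(rt$chain_id)))
}

#' Trim low-confidence terminal residues from each chain
#'
#' From each end of each chain, the maximal contiguous run of residues with
#' pLDDT strictly below `threshold` is removed; low-confidence residues in
#' the chain interior are retained. Chains are trimmed independently. The
#' operation is idempotent. A residue at exactly the threshold is retained
#' (the rule is strict `< threshold`).
#'
#' @param model a [structure_model()].
#' @param profile per-chain confidence profile as returned by
#'   [plddt_profile()]; defaults to extracting it from the model's B-factor
#'   column.
#' @param threshold pLDDT cutoff, default 70.
#' @return the trimmed [structure_model()].
#' @export
trim_low_confidence_termini <- function(model, profile = NULL,
                                        threshold = 70) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(profile)) profile <- plddt_profile(model)
  rt <- .residue_table(model)
  keep_res <- character(0)
  for (ch in unique(rt$chain_id)) {
    res <- rt[rt$chain_id == ch, ]
    p <- profile[[ch]]
    if (is.null(p)) stop("confidence profile missing for chain ", ch)
    if (length(p) != nrow(res)) {
      stop("confidence profile for chain ", ch, " has ", length(p),
           " values but the chain has ", nrow(res), " residues")
    }
    low <- p < threshold
    n <- length(low)
    head_run <- if (low[1]) {
      r <- rle(low)
      r$lengths[1]
    } else 0L
    tail_run <- if (low[n]) {
      r <- rle(rev(low))
      r$lengths[1]
    } else 0L
    if (head_run + tail_run >= n) {
      stop("chain ", ch, " would be removed entirely (all ", n,
           " residues in terminal runs below pLDDT ", threshold,
           "); refusing silent deletion")
    }
    keep <- seq_len(n) > head_run & seq_len(n) <= n - tail_run
    keep_res <- c(keep_res, res$key[keep])
  }
  a <- model$atoms
  akey <- paste(a$chain_id, a$residue_key, sep = "|")
  out <- a[akey %in% keep_res, , drop = FALSE]
  rownames(out) <- NULL
  structure_model(out, model_id = model$model_id,
                  source_format = model$source_format)
}

#' Construct a model score record
#'
#' @param model_id identifier string.
#' @param ptm predicted TM-score in \[0, 1\].
#' @param pae optional predicted-aligned-error matrix (n_res x n_res,
#'   Angstrom).
#' @return an object of class `model_score`.
#' @export
model_score <- function(model_id, ptm, pae = NULL) {
  if (!is.numeric(ptm) || length(ptm) != 1 || is.na(ptm) ||
      ptm < 0 || ptm > 1) {
    stop("ptm must be a single number in [0, 1]")
  }
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) stop("pae matrix must be square")
  }
  structure(list(model_id = model_id, ptm = ptm, pae = pae),
            class = "model_score")
}

#' Read a JSON score file
#'
#' Score files use the schema `{"ptm": <scalar>, "pae": [[...], ...]}` with
#' the PAE matrix row-major, in Angstrom.
#'
#' @param path path to the JSON score file.
#' @param model_id identifier; defaults to the file name.
#' @return a [model_score()].
#' @export
read_model_scores <- function(path, model_id = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$ptm)) stop("score file has no 'ptm' field: ", path)
  model_score(if (is.null(model_id)) basename(path) else model_id,
              ptm = obj$ptm,
              pae = if (!is.null(obj$pae)) obj$pae else NULL)
}

#' Write a JSON score file
#'
#' @param score a [model_score()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_scores <- function(score, path) {
  stopifnot(inherits(score, "model_score"))
  obj <- list(ptm = score$ptm)
  if (!is.null(score$pae)) obj$pae <- score$pae
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Rank predicted models by pTM score
#'
#' @param scores list of [model_score()] objects.
#' @return character vector of model ids, descending by pTM, ties broken by
#'   lexicographic model id (deterministic).
#' @export
rank_models_by_ptm <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 1)
  ids <- vapply(scores, function(s) s$model_id, character(1))
  ptm <- vapply(scores, function(s) s$ptm, numeric(1))
  if (any(ptm < 0 | ptm > 1)) stop("pTM scores must lie in [0, 1]")
  ids[order(-ptm, ids)]
}

#' Mean inter-chain predicted aligned error
#'
#' Summarises interface confidence as the arithmetic mean of the PAE matrix
#' over all ordered residue pairs spanning the two sets, i.e. over both
#' off-diagonal blocks `(i in set1, j in set2)` and `(j, i)`. This fixed
#' summary is a convention of this package; the upstream prediction tools
#' report the full matrix without prescribing a scalar.
#'
#' @param score a [model_score()] with a PAE matrix.
#' @param set1,set2 disjoint integer vectors of residue indices (rows of the
#'   PAE matrix), e.g. antigen and antibody residues.
#' @return mean inter-chain PAE in Angstrom.
#' @export
pae_interface_summary <- function(score, set1, set2) {
  stopifnot(inherits(score, "model_score"))
  if (is.null(score$pae)) stop("model score has no PAE matrix")
  if (length(intersect(set1, set2)) > 0) {
    stop("residue sets must be disjoint")
  }
  n <- nrow(score$pae)
  if (any(c(set1, set2) < 1) || any(c(set1, set2) > n)) {
    stop("residue indices outside PAE matrix dimension ", n)
  }
  mean(c(score$pae[set1, set2], score$pae[set2, set1]))
}

#' Construct a modeling/simulation protocol summary
#'
#' @param n_complexes number of antibody-antigen complexes modeled.
#' @param runs_per_complex prediction runs per complex.
#' @param models_per_run models generated per run.
#' @param replicas_per_complex independent MD replicas per complex.
#' @param duration_per_replica_us duration of each replica in microseconds.
#' @return an object of class `protocol_summary`.
#' @export
protocol_summary <- function(n_complexes, runs_per_complex, models_per_run,
                             replicas_per_complex, duration_per_replica_us) {
  vals <- c(n_complexes, runs_per_complex, models_per_run,
            replicas_per_complex, duration_per_replica_us)
  if (any(vals <= 0)) stop("all protocol counts must be positive")
  structure(list(n_complexes = n_complexes,
                 runs_per_complex = runs_per_complex,
                 models_per_run = models_per_run,
                 replicas_per_complex = replicas_per_complex,
                 duration_per_replica_us = duration_per_replica_us),
            class = "protocol_summary")
}

#' Total model count and total simulated time of a protocol
#'
#' @param summary a [protocol_summary()].
#' @return list with `total_models` (n_complexes x runs x models/run) and
#'   `total_simulated_time_us` (n_complexes x replicas x duration).
#' @export
protocol_totals <- function(summary) {
  stopifnot(inherits(summary, "protocol_summary"))
  list(
    total_models = summary$n_complexes * summary$runs_per_complex *
      summary$models_per_run,
    total_simulated_time_us = summary$n_complexes *
      summary$replicas_per_complex * summary$duration_per_replica_us
  )
}
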