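# Core scoring and selection: per-frame two-state energy differences,
# wild-type-normalized median (the ranking statistic), three-filter
# selection, and rank-stability analysis across conditions.

#' Per-frame two-state energy differences over an ensemble
#'
#' For every frame: strip any bound substrate, build the reactant (ES) and
#' tetrahedral-intermediate (ES*) complex states from the templates, minimize
#' both, and record `delta_e = E(ES*) - E(ES)`. Frames whose minimization
#' diverges are excluded and recorded (never silently dropped); frame indices
#' always refer to the originating ensemble so mutant and wild-type tables
#' stay frame-aligned.
#'
#' @param ensemble an `Ensemble` (wild-type or mutant frames; frame i of a
#'   mutant must derive from frame i of the wild-type ensemble).
#' @param templates substrate templates from [make_substrate_templates()].
#' @param spec an [energy_spec()].
#' @param variant variant label for the table.
#' @param max_iter,grad_tol minimization settings per state.
#' @param es_star_bias constant energy offset added to the ES* state (the
#'   synthetic-effect hook: with frozen geometry it shifts every `delta_e`
#'   by exactly this amount).
#' @return A `DeltaETable` (`variant`, `frame`, `E_ES`, `E_ESstar`,
#'   `delta_e`), with attributes `energy_spec_id`, `frameset_id` and
#'   `excluded` (data.frame of dropped frames and reasons).
#' @export
delta_e_ensemble <- function(ensemble, templates, spec = energy_spec(),
                             variant = "WT", max_iter = 200L, grad_tol = 0.05,
                             es_star_bias = 0) {
  nf <- length(ensemble$members)
  rows <- vector("list", nf)
  excl <- list()
  for (i in seq_len(nf)) {
    prot <- subset_structure(ensemble$members[[i]],
                             which(!ensemble$members[[i]]$atoms$het))
    res <- tryCatch({
      es <- build_state(prot, templates$ES, "ES")
      star <- build_state(prot, templates$ES_STAR, "ES_STAR",
                          restraint_length = templates$ES_STAR$restraint_length,
                          restraint_k = templates$ES_STAR$restraint_k)
      star$bias <- es_star_bias
      m_es <- minimize_state(es, spec, max_iter = max_iter,
                             grad_tol = grad_tol)
      m_star <- minimize_state(star, spec, max_iter = max_iter,
                               grad_tol = grad_tol)
      c(m_es$energy, m_star$energy)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <- data.frame(frame = i, reason = res,
                                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(variant = variant, frame = i, E_ES = res[1L],
                              E_ESstar = res[2L], delta_e = res[2L] - res[1L],
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  attr(df, "energy_spec_id") <- spec$id
  attr(df, "frameset_id") <- ensemble$label
  attr(df, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(frame = integer(0), reason = character(0))
  class(df) <- c("DeltaETable", class(df))
  df
}

#' @rdname delta_e_ensemble
#' @param mutant_ensemble,wt_ensemble frame-aligned ensembles.
#' @export
compute_delta_e <- function(mutant_ensemble, wt_ensemble, templates,
                            spec = energy_spec(), variant = "mutant",
                            max_iter = 200L, grad_tol = 0.05) {
  list(mutant = delta_e_ensemble(mutant_ensemble, templates, spec, variant,
                                 max_iter, grad_tol),
       wt = delta_e_ensemble(wt_ensemble, templates, spec, "WT",
                             max_iter, grad_tol))
}

#' Wild-type-normalized median energy difference
#'
#' The ranking statistic: values below 1 predict transition-state
#' stabilization relative to wild type. Default mode `"per_frame_ratio"`
#' takes the median over shared frames of the per-frame ratio
#' `delta_e_mut / delta_e_wt` (frames with `|delta_e_wt|` below the floor are
#' skipped); mode `"median_of_medians"` is
#' `median(delta_e_mut) / median(delta_e_wt)`. The median mitigates frame
#' outliers.
#'
#' @param mutant,wt `DeltaETable`s sharing frame indices.
#' @param mode normalization mode.
#' @param floor smallest usable `|delta_e_wt|`, kcal/mol.
#' @return The dimensionless statistic, with attribute `mode`; equals 1
#'   exactly when the tables are identical.
#' @export
normalize_median <- function(mutant, wt,
                             mode = c("per_frame_ratio", "median_of_medians"),
                             floor = 1e-6) {
  mode <- match.arg(mode)
  shared <- intersect(mutant$frame, wt$frame)
  if (!length(shared)) stop("no shared valid frames")
  dm <- mutant$delta_e[match(shared, mutant$frame)]
  dw <- wt$delta_e[match(shared, wt$frame)]
  if (mode == "per_frame_ratio") {
    ok <- abs(dw) > floor
    if (!any(ok))
      stop("normalization undefined: all wild-type frames below floor")
    val <- median(dm[ok] / dw[ok])
  } else {
    mw <- median(dw)
    if (abs(mw) <= floor)
      stop("normalization undefined: wild-type median below floor")
    val <- median(dm) / mw
  }
  attr(val, "mode") <- mode
  val
}

#' Minimum heavy-atom distance between a residue and the substrate
#'
#' Measured on the seed-frame reactant complex; the proximity filter accepts
#' residues closer than 5 A.
#'
#' @param complex a `Structure` containing both protein and HETATM substrate.
#' @param res_id protein residue id.
#' @param chain protein chain.
#' @return Distance in Angstrom.
#' @export
min_substrate_distance <- function(complex, res_id, chain = "A") {
  a <- complex$atoms
  ri <- which(a$chain == chain & a$res_id == res_id & !a$het &
                toupper(a$element) != "H")
  si <- which(a$het & toupper(a$element) != "H")
  if (!length(ri)) stop("residue ", res_id, " not found")
  if (!length(si)) stop("no substrate atoms present")
  min(sqrt(outer(rowSums(complex$xyz[ri, , drop = FALSE]^2),
                 rowSums(complex$xyz[si, , drop = FALSE]^2), "+") -
             2 * complex$xyz[ri, , drop = FALSE] %*%
             t(complex$xyz[si, , drop = FALSE])))
}

#' Apply the three selection filters and rank variants
#'
#' A candidate passes iff (strictly) its normalized energy statistic is below
#' `delta_e`, its conservation score above `pssm`, and its substrate distance
#' below `distance`. All candidates are ranked ascending by the energy
#' statistic, ties broken lexicographically by name.
#'
#' @param candidates data.frame with columns `name`, `delta_e_norm`,
#'   `pssm_score`, `min_substrate_distance`.
#' @param thresholds list: `delta_e` (default 0.985), `pssm` (-4.0),
#'   `distance` (5.0 A).
#' @return The input with `pass_energy`, `pass_pssm`, `pass_distance`,
#'   `passes` and `rank` columns, sorted by rank.
#' @export
apply_filters <- function(candidates,
                          thresholds = list(delta_e = 0.985, pssm = -4.0,
                                            distance = 5.0)) {
  need <- c("name", "delta_e_norm", "pssm_score", "min_substrate_distance")
  miss <- setdiff(need, names(candidates))
  if (length(miss) || anyNA(candidates[, intersect(need, names(candidates))]))
    stop("incomplete candidate: missing ", paste(miss, collapse = ", "))
  th <- merge_config(list(delta_e = 0.985, pssm = -4.0, distance = 5.0),
                     thresholds)
  out <- candidates
  out$pass_energy <- out$delta_e_norm < th$delta_e
  out$pass_pssm <- out$pssm_score > th$pssm
  out$pass_distance <- out$min_substrate_distance < th$distance
  out$passes <- out$pass_energy & out$pass_pssm & out$pass_distance
  ord <- order(out$delta_e_norm, out$name)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}

# delta-e-norm vector for a set of tables restricted to given frames
delta_e_norm_subset <- function(wt, variants, frames = NULL,
                                mode = "per_frame_ratio") {
  take <- function(tb) {
    if (is.null(frames)) tb else tb[tb$frame %in% frames, , drop = FALSE]
  }
  wts <- take(wt)
  vapply(variants, function(tb) as.numeric(normalize_median(take(tb), wts,
                                                            mode = mode)),
         numeric(1L))
}

#' Rank stability across conditions and frame subsets
#'
#' Recomputes the normalized energy statistic of every variant under each
#' condition (e.g. different energy-model parameterizations) and, within each
#' condition, under `n_subsamples` random frame subsets drawn without
#' replacement. Reports the pairwise Spearman correlation of the resulting
#' rank vectors and the top-k overlap fraction, over all condition x
#' subsample instances.
#'
#' @param conditions named list; each element is a list with `wt` (a
#'   `DeltaETable`) and `variants` (named list of `DeltaETable`s, >= 3
#'   variants). A single condition may be passed directly.
#' @param n_subsamples frame subsets per condition (0 = use all frames once).
#' @param subsample_frames frames per subset (default 12, an eighth of the
#'   96-frame design ensemble).
#' @param top_k k for the top-k overlap fraction.
#' @param mode normalization mode passed to [normalize_median()].
#' @param rng_seed integer seed (subsampling is deterministic per seed).
#' @return A `StabilityReport`: list with `rho` (correlation matrix over
#'   instances), `mean_rho` (mean off-diagonal), `topk` matrix, `mean_topk`,
#'   `instances` (labels), `delta_e_norm` (matrix instances x variants).
#' @export
rank_stability <- function(conditions, n_subsamples = 20L,
                           subsample_frames = 12L, top_k = 3L,
                           mode = "per_frame_ratio", rng_seed = 1L) {
  if (!is.null(conditions$wt)) conditions <- list(condition = conditions)
  nv <- length(conditions[[1L]]$variants)
  if (nv < 3L) stop("insufficient variants: need >= 3")
  vnames <- names(conditions[[1L]]$variants)

  inst <- list()
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    frames_all <- cond$wt$frame
    if (n_subsamples < 1L) {
      inst[[cn]] <- delta_e_norm_subset(cond$wt, cond$variants, NULL, mode)
    } else {
      if (subsample_frames > length(frames_all))
        stop("subsample_frames exceeds available frames")
      for (s in seq_len(n_subsamples)) {
        set.seed(substream(rng_seed, paste0("stability_", cn, "_", s)))
        fr <- sample(frames_all, subsample_frames)
        inst[[paste0(cn, "#", s)]] <-
          delta_e_norm_subset(cond$wt, cond$variants, fr, mode)
      }
    }
  }
  m <- do.call(rbind, inst)   # instances x variants
  colnames(m) <- vnames
  rho <- cor(apply(m, 1L, rank))   # columns = instances, rows = variants
  k <- min(top_k, nv)
  tops <- apply(m, 1L, function(x) vnames[order(x)][seq_len(k)],
                simplify = FALSE)
  ni <- nrow(m)
  topk <- matrix(1, ni, ni, dimnames = dimnames(rho))
  for (i in seq_len(ni)) for (j in seq_len(ni))
    topk[i, j] <- length(intersect(tops[[i]], tops[[j]])) / k
  off <- upper.tri(rho)
  structure(list(rho = rho, mean_rho = mean(rho[off]), topk = topk,
                 mean_topk = mean(topk[off]), instances = rownames(m),
                 delta_e_norm = m, mode = mode, top_k = k,
                 n_subsamples = n_subsamples,
                 subsample_frames = subsample_frames, rng_seed = rng_seed),
            class = "StabilityReport")
}

#' Write a ranked-variant table as TSV
#'
#' @param ranked an [apply_filters()] result.
#' @param path output file.
#' @export
write_ranked_tsv <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
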