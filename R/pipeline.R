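# End-to-end orchestration: ensemble -> mutate -> two-state minimize ->
# normalized energy statistic -> filters -> rank -> stability, plus the
# structural/H-bond resolution suite for user-supplied model ensembles.

default_run_config <- function() {
  list(
    seed = list(type = "toy", n_res = 20L, path = NULL),
    rng_seed = 1L,
    n_conformers = 8L,
    bounds = list(),
    variants = NULL,                     # NULL = auto-pick near-substrate Ala
    n_auto_variants = 4L,
    energy_specs = list(
      list(id = "default"),
      list(id = "alt_substrate", lj_scale = 0.8, charge_scale = 1.25)),
    minimize = list(max_iter = 150L, grad_tol = 0.05),
    restraint = list(length = 1.9, k = 200),
    msa = list(n_seqs = 200L, conservation = 0.6, triad_conservation = 0.95),
    pssm = list(pseudocount = 1),
    thresholds = list(delta_e = 0.985, pssm = -4.0, distance = 5.0),
    stability = list(n_subsamples = 5L, subsample_frames = 4L, top_k = 3L),
    hbond = list(max_distance = 3.0, min_angle = 150,
                 fallback = "ideal_h"),
    out_dir = NULL
  )
}

#' Read and validate a run configuration
#'
#' @param path YAML file; keys as in the package default config (see
#'   [run_design()]). Unknown top-level keys are rejected before any compute.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(default_run_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("config error: unknown key(s) ", paste(bad, collapse = ", "))
  if (!is.null(cfg$n_conformers) && cfg$n_conformers < 1)
    stop("config error: n_conformers must be >= 1")
  if (!is.null(cfg$rng_seed)) cfg$rng_seed <- as.integer(cfg$rng_seed)
  merge_config(default_run_config(), cfg)
}

# hash of the scientific configuration (output location excluded)
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg, tf, version = 2L)
  unname(tools::md5sum(tf))
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

spec_from_list <- function(sl) do.call(energy_spec, sl)

auto_variants <- function(toy, n = 4L) {
  meta <- attr(toy, "meta")
  a <- toy$atoms
  ala <- sort(unique(a$res_id[!a$het & a$res_name == "ALA"]))
  d <- vapply(ala, function(r) min_substrate_distance(toy, r), numeric(1L))
  picks <- ala[order(d)][seq_len(min(n, length(ala)))]
  tos <- rep_len(c("G", "V", "S", "L"), length(picks))
  paste0("A", picks, tos)
}

#' Run the ensemble-based design protocol end to end
#'
#' Stages, in order: seed structure (generated toy enzyme or a PDB path),
#' design-ensemble generation under distance bounds with triad anchoring,
#' variant construction (side-chain rebuild per frame), two-state minimization
#' and per-frame energy differences for the wild type and every variant under
#' each configured energy spec, wild-type-normalized median statistics,
#' conservation scores from a (generated or supplied) alignment, substrate
#' proximity, the three-filter ranking, rank-stability analysis across energy
#' specs and frame subsets, and structural/H-bond resolution summaries.
#' Any stage failure aborts with the stage name; the run is deterministic for
#' a given (config, rng_seed).
#'
#' @param config a config list (see package default) or a YAML path for
#'   [read_run_config()].
#' @return A `RunReport` list: `ranked`, `stability`, `delta_e`, `occupancy`,
#'   `rmsf`, `rmsd_ca`, `rmsd_active_site`, `exclusions`, `timings`,
#'   `config_hash`, `rng_seed`, `variants`, `ground_truth` (seed metadata).
#'   When `config$out_dir` is set, TSV/JSON/PDB artifacts are written there.
#' @export
run_design <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  hash <- config_hash(cfg)
  seed_int <- as.integer(cfg$rng_seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  toy <- with_stage("seed_structure", {
    if (!is.null(cfg$seed$path)) {
      ens <- read_structure(cfg$seed$path)
      ens$members[[1L]]
    } else make_toy_enzyme(cfg$seed$n_res, rng_seed = seed_int)
  })
  meta <- attr(toy, "meta")
  timings["seed_structure"] <- tic() - t0; t0 <- tic()

  ensemble <- with_stage("ensemble", build_design_ensemble(
    toy, n_conformers = cfg$n_conformers, config = cfg$bounds,
    rng_seed = seed_int))
  timings["ensemble"] <- tic() - t0; t0 <- tic()

  vnames <- cfg$variants
  if (is.null(vnames)) vnames <- auto_variants(toy, cfg$n_auto_variants)
  mut_ens <- with_stage("mutagenesis", {
    out <- lapply(vnames, function(v) apply_variant(ensemble, v))
    names(out) <- vnames
    out
  })
  timings["mutagenesis"] <- tic() - t0; t0 <- tic()

  templates <- with_stage("substrate_templates", make_substrate_templates(
    toy, restraint_length = cfg$restraint$length,
    restraint_k = cfg$restraint$k))

  specs <- lapply(cfg$energy_specs, spec_from_list)
  names(specs) <- vapply(specs, function(s) s$id, character(1L))
  dtables <- with_stage("delta_e", {
    out <- list()
    for (sp in specs) {
      wt_tb <- delta_e_ensemble(ensemble, templates, sp, "WT",
                                max_iter = cfg$minimize$max_iter,
                                grad_tol = cfg$minimize$grad_tol)
      vt <- lapply(vnames, function(v)
        delta_e_ensemble(mut_ens[[v]], templates, sp, v,
                         max_iter = cfg$minimize$max_iter,
                         grad_tol = cfg$minimize$grad_tol))
      names(vt) <- vnames
      out[[sp$id]] <- list(wt = wt_tb, variants = vt)
    }
    out
  })
  timings["delta_e"] <- tic() - t0; t0 <- tic()

  msa_obj <- with_stage("msa", {
    cons <- rep(cfg$msa$conservation, cfg$seed$n_res)
    if (!is.null(meta$triad)) cons[meta$triad] <- cfg$msa$triad_conservation
    make_msa(length = length(meta$sequence), n_seqs = cfg$msa$n_seqs,
             conservation = cons, rng_seed = seed_int,
             consensus = meta$sequence)
  })
  pssm <- compute_pssm(msa_obj$msa, pseudocount = cfg$pssm$pseudocount)

  ranked <- with_stage("rank_filter", {
    first <- dtables[[1L]]
    cand <- data.frame(
      name = vnames,
      delta_e_norm = vapply(vnames, function(v)
        as.numeric(normalize_median(first$variants[[v]], first$wt)),
        numeric(1L)),
      pssm_score = vapply(vnames, function(v) {
        sp <- parse_variant(v)[[1L]]
        score_mutation(pssm, sp$res_id, sp$to)
      }, numeric(1L)),
      min_substrate_distance = vapply(vnames, function(v)
        min_substrate_distance(toy, parse_variant(v)[[1L]]$res_id),
        numeric(1L)),
      stringsAsFactors = FALSE)
    apply_filters(cand, cfg$thresholds)
  })
  timings["rank_filter"] <- tic() - t0; t0 <- tic()

  stability <- with_stage("stability", rank_stability(
    dtables, n_subsamples = cfg$stability$n_subsamples,
    subsample_frames = cfg$stability$subsample_frames,
    top_k = cfg$stability$top_k, rng_seed = seed_int))
  timings["stability"] <- tic() - t0; t0 <- tic()

  resolution <- with_stage("resolution", {
    crit <- hbond_criteria(cfg$hbond$max_distance, cfg$hbond$min_angle,
                           cfg$hbond$fallback)
    oxy <- c(meta$ser + 1L, meta$ser + 2L)
    defns <- canonical_hbonds(oxyanion_res = oxy, ser = meta$ser,
                              his = meta$his, asp = meta$asp)
    occ <- hbond_occupancy(ensemble, defns, crit)
    active_res <- sort(unique(c(meta$triad, oxy)))
    list(occupancy = occ, rmsf = rmsf_profile(ensemble),
         rmsd_ca = pairwise_rmsd_matrix(ensemble),
         rmsd_active_site = pairwise_rmsd_matrix(
           ensemble, selection_backbone(active_res)))
  })
  timings["resolution"] <- tic() - t0

  excl_of <- function(tb, v, id) {
    ex <- attr(tb, "excluded")
    if (is.null(ex) || nrow(ex) == 0L) return(NULL)
    cbind(energy_spec = id, variant = v, ex)
  }
  exclusions <- do.call(rbind, unlist(lapply(names(dtables), function(id) {
    c(list(excl_of(dtables[[id]]$wt, "WT", id)),
      lapply(vnames, function(v)
        excl_of(dtables[[id]]$variants[[v]], v, id)))
  }), recursive = FALSE))

  report <- list(ranked = ranked, stability = stability, delta_e = dtables,
                 occupancy = resolution$occupancy, rmsf = resolution$rmsf,
                 rmsd_ca = resolution$rmsd_ca,
                 rmsd_active_site = resolution$rmsd_active_site,
                 exclusions = exclusions, timings = timings,
                 config_hash = hash, rng_seed = seed_int, variants = vnames,
                 meta = meta)
  class(report) <- "RunReport"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ranked_tsv(ranked, file.path(cfg$out_dir, "ranked_variants.tsv"))
    jsonlite::write_json(
      list(config_hash = hash, rng_seed = seed_int,
           mean_rho = stability$mean_rho, mean_topk = stability$mean_topk,
           instances = stability$instances),
      file.path(cfg$out_dir, "stability_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(resolution$occupancy,
                file.path(cfg$out_dir, "occupancy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_structure(ensemble, file.path(cfg$out_dir, "design_ensemble.pdb"))
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (config", substr(x$config_hash, 1L, 8L), ", seed",
      x$rng_seed, ")\n")
  cat("ranked variants:\n")
  print(x$ranked[, c("name", "delta_e_norm", "pssm_score",
                     "min_substrate_distance", "passes", "rank")])
  cat(sprintf("rank stability: mean Spearman rho %.3f, mean top-%d overlap %.3f over %d instances\n",
              x$stability$mean_rho, x$stability$top_k, x$stability$mean_topk,
              length(x$stability$instances)))
  invisible(x)
}

#' Structural/H-bond resolution suite for supplied model ensembles
#'
#' Applies the downstream analyses to externally produced structures (e.g.
#' predicted models shipped as multi-model PDB): pairwise C-alpha and
#' active-site backbone RMSD matrices across variants, per-variant RMSF when
#' multiple frames are available, hydrogen-bond occupancy per variant, and
#' (when an activity table is given) occupancy-activity association.
#'
#' @param inputs named list of `Ensemble`s or PDB paths, one per variant
#'   (>= 2); members of each input must be topology-identical.
#' @param active_site_res residues of the active-site backbone selection
#'   (default 16, 82, 83, 229, 251).
#' @param defns optional list of [hbond_definition()]s; occupancy is skipped
#'   when `NULL`.
#' @param crit an [hbond_criteria()].
#' @param activity optional activity table (columns `variant`, `activity` or
#'   `roche_activity_pct`).
#' @param n_perm,rng_seed association-test settings.
#' @return List with `rmsd_ca`, `rmsd_active_site`, `rmsf`, `occupancy`,
#'   `association`.
#' @export
run_resolution_suite <- function(inputs,
                                 active_site_res = c(16L, 82L, 83L, 229L, 251L),
                                 defns = NULL, crit = hbond_criteria(),
                                 activity = NULL, n_perm = 10000L,
                                 rng_seed = 1L) {
  if (length(inputs) < 2L) stop("need >= 2 input structures/ensembles")
  if (is.null(names(inputs)))
    names(inputs) <- paste0("model", seq_along(inputs))
  ens <- lapply(names(inputs), function(nm) {
    x <- inputs[[nm]]
    e <- if (is.character(x)) read_structure(x, label = nm) else x
    if (inherits(e, "Structure")) e <- new_ensemble(list(e), label = nm)
    e$label <- nm
    for (k in seq_along(e$members)) e$members[[k]]$label <- nm
    e
  })
  names(ens) <- names(inputs)

  rep1 <- lapply(ens, function(e) e$members[[1L]])
  ref_key <- atom_key(rep1[[1L]]$atoms)
  for (k in seq_along(rep1))
    if (!identical(atom_key(rep1[[k]]$atoms), ref_key))
      stop("alignment-map error: input ", names(ens)[k],
           " does not share the atom set of input 1")

  rmsd_ca <- pairwise_rmsd_matrix(rep1, selection_ca())
  rmsd_as <- pairwise_rmsd_matrix(rep1, selection_backbone(active_site_res))
  rmsf <- lapply(ens, function(e)
    if (length(e$members) >= 2L) rmsf_profile(e) else NULL)

  occupancy <- NULL
  association <- NULL
  if (!is.null(defns)) {
    occupancy <- do.call(rbind, lapply(names(ens), function(nm)
      cbind(variant = nm, step = "models",
            hbond_occupancy(ens[[nm]], defns, crit))))
    if (!is.null(activity))
      association <- activity_association(
        occupancy[occupancy$bond != "all", c("variant", "step", "bond",
                                             "frequency_pct")],
        activity, n_perm = n_perm, rng_seed = rng_seed)
  }
  list(rmsd_ca = rmsd_ca, rmsd_active_site = rmsd_as, rmsf = rmsf,
       occupancy = occupancy, association = association)
}
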