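# Distance-geometry conformer generation: structure-derived distance bounds
# with catalytic-triad anchoring, sampled by random perturbation plus
# iterative pairwise bound projection.

covalent_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, CL = 1.02, BR = 1.2, I = 1.39)

elem_radius <- function(element, table = covalent_radius) {
  r <- table[toupper(element)]
  r[is.na(r)] <- 0.76
  unname(r)
}

# adjacency from interatomic distances: bonded if d <= 1.25 * (r_i + r_j)
covalent_adjacency <- function(x) {
  d <- as.matrix(stats::dist(x$xyz))
  r <- elem_radius(x$atoms$element)
  cut <- 1.25 * outer(r, r, "+")
  adj <- d <= cut & d > 0
  # no bonds across chains (protein vs substrate unless genuinely in range)
  adj
}

default_bound_config <- function() {
  list(tol_bond12 = 0.05, tol_angle13 = 0.10, tol_dihedral14 = 0.30,
       contact_cutoff = 6.0, tol_contact = 0.50, tol_anchor = 0.05,
       anchor_residues = NULL, anchor_include_het = TRUE,
       perturb_sigma = 0.8, satisfy_tol = 0.01, max_sweeps = 5000L)
}

merge_config <- function(defaults, config) {
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

#' Derive distance bounds from a seed structure
#'
#' Builds the bound set that defines the conformer ensemble: covalent (1-2),
#' angle (1-3) and dihedral (1-4) distances bounded at the seed value plus or
#' minus a per-class tolerance, heavy-atom contact bounds inside a cutoff, and
#' tight anchor bounds over all pairs of the anchored atom set (by default the
#' catalytic-triad side chains plus any bound substrate/HETATM atoms), which
#' preserve the active-site/transition-state geometry of the seed.
#'
#' @param seed a `Structure`; the seed satisfies every derived bound by
#'   construction.
#' @param config named list overriding [defaults][derive_bounds]:
#'   `tol_bond12` (0.05 A), `tol_angle13` (0.10), `tol_dihedral14` (0.30),
#'   `contact_cutoff` (6.0), `tol_contact` (0.50), `tol_anchor` (0.05),
#'   `anchor_residues` (integer res_ids; `NULL` uses the seed's `triad`
#'   metadata when present), `anchor_include_het`, `perturb_sigma`,
#'   `satisfy_tol`, `max_sweeps`.
#' @return A `BoundSet`: list with `bounds` (data.frame `i`, `j`, `lower`,
#'   `upper`, `klass`), `seed`, `config`.
#' @export
derive_bounds <- function(seed, config = list()) {
  cfg <- merge_config(default_bound_config(), config)
  if (is.null(cfg$anchor_residues)) {
    meta <- attr(seed, "meta")
    if (!is.null(meta$triad)) cfg$anchor_residues <- meta$triad
  }
  a <- seed$atoms
  heavy <- toupper(a$element) != "H"
  d <- as.matrix(stats::dist(seed$xyz))
  adj <- covalent_adjacency(seed)

  n <- nrow(a)
  A <- adj * 1L
  A2 <- (A %*% A) > 0
  A3 <- (A %*% A %*% A) > 0
  ut <- upper.tri(d)

  is12 <- adj & ut
  is13 <- A2 & !adj & ut; diag(is13) <- FALSE
  is13 <- is13 & ut
  is14 <- A3 & !A2 & !adj & ut

  # anchored atom set: side-chain heavy atoms of anchor residues + HETATM
  anchor_atoms <- logical(n)
  if (length(cfg$anchor_residues)) {
    miss <- setdiff(as.integer(cfg$anchor_residues), a$res_id)
    if (length(miss))
      stop("config error: anchored residue(s) absent from seed: ",
           paste(miss, collapse = ", "))
    anchor_atoms <- a$res_id %in% cfg$anchor_residues &
      !(a$name %in% c("N", "CA", "C", "O", "OXT")) & heavy
    if (isTRUE(cfg$anchor_include_het)) anchor_atoms <- anchor_atoms | (a$het & heavy)
  }
  in_anchor <- outer(anchor_atoms, anchor_atoms, "&") & ut

  hv <- outer(heavy, heavy, "&")
  contact <- hv & ut & d <= cfg$contact_cutoff & !adj & !A2 & !A3 & !in_anchor

  emit <- function(mask, tol, klass) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L)
      return(data.frame(i = integer(0), j = integer(0), lower = numeric(0),
                        upper = numeric(0), klass = character(0)))
    dd <- d[idx]
    data.frame(i = idx[, 1L], j = idx[, 2L],
               lower = pmax(dd - tol, 1e-3), upper = dd + tol,
               klass = klass, stringsAsFactors = FALSE)
  }
  bounds <- rbind(
    emit(is12, cfg$tol_bond12, "bond12"),
    emit(is13, cfg$tol_angle13, "angle13"),
    emit(is14 & !in_anchor, cfg$tol_dihedral14, "dihedral14"),
    emit(contact, cfg$tol_contact, "contact"),
    emit(in_anchor & !adj & !A2, cfg$tol_anchor, "anchor")
  )
  rownames(bounds) <- NULL
  structure(list(bounds = bounds, seed = seed, config = cfg),
            class = "BoundSet")
}

#' Largest bound violation of a structure
#'
#' Re-measures every bound in a `BoundSet` against a structure's coordinates.
#'
#' @param x a `Structure` with the bound set's topology.
#' @param boundset a [derive_bounds()] result.
#' @return Largest violation in Angstrom (0 when all bounds hold).
#' @export
check_bounds <- function(x, boundset) {
  b <- boundset$bounds
  dx <- x$xyz[b$i, , drop = FALSE] - x$xyz[b$j, , drop = FALSE]
  dd <- sqrt(rowSums(dx^2))
  max(0, b$lower - dd, dd - b$upper)
}

#' Generate one conformer satisfying a bound set
#'
#' Perturbs the seed coordinates with isotropic Gaussian noise and restores
#' bound satisfaction by sequential pairwise projection sweeps (random bound
#' order per sweep) until every bound holds within the satisfaction tolerance
#' or the sweep cap is reached. Projection from a random start can land in a
#' locally infeasible basin (the bound set itself is always satisfiable: the
#' seed satisfies it), so a stuck run is restarted with a fresh perturbation,
#' shrinking its amplitude on later attempts; the whole procedure is
#' deterministic for a given `rng_seed`.
#'
#' @param boundset a [derive_bounds()] result.
#' @param rng_seed integer seed.
#' @param max_attempts perturbation restarts before giving up.
#' @return A `Structure`; non-convergence raises an error reporting the worst
#'   remaining violation.
#' @export
generate_conformer <- function(boundset, rng_seed = 1L, max_attempts = 8L) {
  cfg <- boundset$config
  seed <- boundset$seed
  n <- nrow(seed$xyz)
  b <- boundset$bounds
  res <- NULL
  for (att in seq_len(max_attempts)) {
    aseed <- substream(rng_seed, sprintf("conformer_attempt_%d", att))
    set.seed(aseed)
    sigma <- cfg$perturb_sigma * 0.85^(att - 1L)
    X <- seed$xyz + matrix(rnorm(3L * n, sd = sigma), n, 3L)
    res <- cpp_solve_bounds(X, as.integer(b$i - 1L), as.integer(b$j - 1L),
                            b$lower, b$upper, cfg$satisfy_tol * 0.5,
                            as.integer(cfg$max_sweeps), aseed)
    if (res$max_violation <= cfg$satisfy_tol)
      return(new_structure(seed$atoms, res$coords,
                           label = sprintf("conformer_%d", rng_seed)))
  }
  stop(sprintf(
    "non-convergence: worst bound violation %.4f A after %d attempts x %d sweeps",
    res$max_violation, max_attempts, cfg$max_sweeps))
}

#' Assemble the design ensemble (seed plus generated conformers)
#'
#' Member 1 is the unmodified seed structure; members 2..(n+1) are conformers
#' generated with seeds `rng_seed + 1 .. rng_seed + n`. With the protocol
#' default of 95 conformers this yields the 96-member design ensemble.
#'
#' @param seed a `Structure`.
#' @param n_conformers number of conformers to generate (>= 1).
#' @param config bound/generation config passed to [derive_bounds()].
#' @param rng_seed integer base seed.
#' @return An `Ensemble` of `n_conformers + 1` members.
#' @export
build_design_ensemble <- function(seed, n_conformers = 95L, config = list(),
                                  rng_seed = 1L) {
  if (n_conformers < 1L)
    stop("config error: n_conformers must be >= 1")
  bs <- derive_bounds(seed, config)
  members <- vector("list", n_conformers + 1L)
  s0 <- seed
  s0$label <- if (nzchar(seed$label)) seed$label else "seed"
  members[[1L]] <- s0
  for (k in seq_len(n_conformers)) {
    members[[k + 1L]] <- tryCatch(
      generate_conformer(bs, rng_seed = rng_seed + k),
      error = function(e) stop("conformer ", k, ": ", conditionMessage(e)))
  }
  new_ensemble(members, label = "design_ensemble")
}
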