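# Two-state (reactant ES / tetrahedral-intermediate ES*) complex construction
# and a swappable pairwise molecular-mechanics energy model with
# steepest-descent minimization. The model is a documented simplification:
# Lennard-Jones + Coulomb with a distance-dependent dielectric, harmonic
# covalent-bond and 1-3 (Urey-Bradley) distance terms, and a harmonic
# Ser-Ogamma -- carbonyl-C restraint in the ES* state. Fidelity target is
# ordinal behaviour of variant rankings, not force-field energies; the spec
# object exists precisely so rankings can be recomputed under different
# parameterizations.

LJ_EPS <- c(C = 0.086, N = 0.170, O = 0.210, S = 0.250, H = 0.0157, P = 0.2)
LJ_RMIN2 <- c(C = 1.908, N = 1.824, O = 1.661, S = 2.000, H = 0.600, P = 2.1)

BACKBONE_CHARGE <- c(N = -0.4157, CA = 0.0337, C = 0.5973, O = -0.5679,
                     OXT = -0.5679)
SUBSTRATE_CHARGE <- c(C1 = 0.55, O1 = -0.50, O2 = -0.40, C2 = 0.10,
                      C3 = 0.05, O3 = -0.45)

#' Energy model specification
#'
#' Parameter set for [evaluate_energy()]/[minimize_state()]. Distinct specs
#' are first-class values so mutation rankings can be recomputed under
#' different substrate/nonbonded parameterizations (the rank-stability
#' analysis swaps them).
#'
#' @param id spec label.
#' @param lj_scale,charge_scale multipliers on all LJ well depths / partial
#'   charges (the simplest re-parameterization knobs).
#' @param lj_eps,lj_rmin2 named per-element LJ well depths (kcal/mol) and
#'   rmin/2 radii (Angstrom).
#' @param dielectric `"4r"` (distance-dependent, default) or `"constant"`.
#' @param eps_const dielectric constant when `dielectric = "constant"`.
#' @param coulomb_k Coulomb constant, kcal A / (mol e^2).
#' @param bonded logical; include harmonic bond/1-3 terms.
#' @param k_bond,k_13 harmonic force constants, kcal/mol/A^2.
#' @param restraint_k default ES* covalent-restraint force constant.
#' @param substrate_charges named charges for substrate atoms (a substrate
#'   parameterization; swapping it is one of the stability conditions).
#' @return An `EnergyModelSpec` list.
#' @export
energy_spec <- function(id = "default", lj_scale = 1, charge_scale = 1,
                        lj_eps = LJ_EPS, lj_rmin2 = LJ_RMIN2,
                        dielectric = c("4r", "constant"), eps_const = 4,
                        coulomb_k = 332.0636, bonded = TRUE,
                        k_bond = 300, k_13 = 80, restraint_k = 200,
                        substrate_charges = SUBSTRATE_CHARGE) {
  structure(list(id = id, lj_scale = lj_scale, charge_scale = charge_scale,
                 lj_eps = lj_eps, lj_rmin2 = lj_rmin2,
                 dielectric = match.arg(dielectric), eps_const = eps_const,
                 coulomb_k = coulomb_k, bonded = bonded, k_bond = k_bond,
                 k_13 = k_13, restraint_k = restraint_k,
                 substrate_charges = substrate_charges),
            class = "EnergyModelSpec")
}

assign_charges <- function(x, spec) {
  a <- x$atoms
  q <- numeric(nrow(a))
  bb <- match(a$name, names(BACKBONE_CHARGE))
  q[!is.na(bb) & !a$het] <- BACKBONE_CHARGE[bb[!is.na(bb) & !a$het]]
  sc <- is.na(bb) & !a$het
  first <- toupper(substring(a$name, 1L, 1L))
  q[sc & first == "O"] <- -0.50
  q[sc & first == "N"] <- -0.40
  q[sc & first == "S"] <- -0.20
  sub <- a$het
  m <- match(a$name[sub], names(spec$substrate_charges))
  qs <- unname(spec$substrate_charges[m])
  qs[is.na(qs)] <- 0
  q[sub] <- qs
  q * spec$charge_scale
}

#' Pair topology for energy evaluation
#'
#' Derives covalent bonds from the reference geometry, excludes 1-2 and 1-3
#' pairs from the nonbonded list, and sets harmonic reference distances from
#' `reference` (by default the structure itself, i.e. a structure-restrained
#' relaxation; pass a different reference to pull bonds toward other values).
#'
#' @param x `Structure` to be evaluated.
#' @param spec an [energy_spec()].
#' @param reference `Structure` supplying harmonic reference distances.
#' @return An `EnergyTopology` list used by [evaluate_energy()].
#' @export
energy_topology <- function(x, spec = energy_spec(), reference = x) {
  n <- nrow(x$atoms)
  adj <- covalent_adjacency(reference)
  A2 <- (adj %*% adj) > 0
  ut <- upper.tri(adj)
  dref <- as.matrix(stats::dist(reference$xyz))

  b12 <- which(adj & ut, arr.ind = TRUE)
  b13 <- which(A2 & !adj & ut & row(adj) != col(adj), arr.ind = TRUE)
  harm <- data.frame(
    i = c(b12[, 1L], b13[, 1L]), j = c(b12[, 2L], b13[, 2L]),
    r0 = c(dref[b12], dref[b13]),
    k = c(rep(spec$k_bond, nrow(b12)), rep(spec$k_13, nrow(b13))))
  if (!spec$bonded) harm <- harm[0, ]

  excl <- adj | A2
  nb <- which(!excl & ut, arr.ind = TRUE)
  q <- assign_charges(x, spec)
  eps_el <- spec$lj_eps[toupper(x$atoms$element)]
  eps_el[is.na(eps_el)] <- spec$lj_eps[["C"]]
  rm2 <- spec$lj_rmin2[toupper(x$atoms$element)]
  rm2[is.na(rm2)] <- spec$lj_rmin2[["C"]]

  structure(list(
    nb_i = nb[, 1L], nb_j = nb[, 2L],
    qq = q[nb[, 1L]] * q[nb[, 2L]],
    eps = spec$lj_scale * sqrt(eps_el[nb[, 1L]] * eps_el[nb[, 2L]]),
    rmin = rm2[nb[, 1L]] + rm2[nb[, 2L]],
    harm = harm, n_atoms = n), class = "EnergyTopology")
}

# ---- complex states ---------------------------------------------------------

#' Build a reactant (ES) or tetrahedral-intermediate (ES*) complex state
#'
#' Places the substrate template into the protein frame by rigidly aligning
#' the template's three anchor reference atoms (protein atoms whose positions
#' were recorded when the template was made) onto the same atoms of the given
#' protein structure. The ES* state registers a harmonic covalent restraint
#' between the catalytic serine Ogamma and the substrate carbonyl carbon at
#' the configured target length (default 1.9 A, the ester-addition
#' transition-state value); ES carries no restraint.
#'
#' @param protein a `Structure` (protein only).
#' @param template a substrate template, e.g. from
#'   [make_substrate_templates()]: list with `structure` (substrate fragment),
#'   `ref_atoms` (data.frame chain/res_id/name of 3 non-collinear protein
#'   atoms), `ref_coords` (their 3 x 3 coordinates at template creation) and
#'   `restraint` (protein atom spec + substrate atom name).
#' @param state `"ES"` or `"ES_STAR"`.
#' @param restraint_length target Ogamma-C length for ES*, Angstrom.
#' @param restraint_k harmonic force constant, kcal/mol/A^2.
#' @return A `ComplexState`: list with `structure` (protein + substrate),
#'   `state`, `restraint` (`NULL` for ES) and `bias` (energy offset, 0).
#' @export
build_state <- function(protein, template, state = c("ES", "ES_STAR"),
                        restraint_length = 1.9, restraint_k = 200) {
  state <- match.arg(state)
  ra <- template$ref_atoms
  idx <- integer(nrow(ra))
  for (k in seq_len(nrow(ra))) {
    hit <- which(protein$atoms$chain == ra$chain[k] &
                   protein$atoms$res_id == ra$res_id[k] &
                   protein$atoms$name == ra$name[k])
    if (length(hit) != 1L)
      stop("template error: anchor atom ", ra$name[k], " of residue ",
           ra$res_id[k], " missing from protein")
    idx[k] <- hit
  }
  Q <- protein$xyz[idx, , drop = FALSE]
  P <- template$ref_coords
  sv <- svd(sweep(P, 2L, colMeans(P)))$d
  if (sv[2L] < 1e-6 * max(sv[1L], 1))
    stop("degenerate frame: anchor atoms are collinear")
  fit <- kabsch_fit(P, Q)
  sub <- template$structure
  sub_xyz <- sweep(sub$xyz %*% t(fit$rotation), 2L, fit$translation, "+")

  atoms <- rbind(protein$atoms, sub$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  combined <- new_structure(atoms, rbind(protein$xyz, sub_xyz),
                            label = paste0(protein$label, "+substrate"))
  restraint <- NULL
  if (state == "ES_STAR") {
    rp <- template$restraint
    i <- which(combined$atoms$chain == rp$protein$chain &
                 combined$atoms$res_id == rp$protein$res_id &
                 combined$atoms$name == rp$protein$name)
    j <- which(combined$atoms$het & combined$atoms$name == rp$substrate)
    if (length(i) != 1L || length(j) != 1L)
      stop("template error: restraint atoms not found")
    restraint <- list(i = i, j = j, target = restraint_length, k = restraint_k)
  }
  structure(list(structure = combined, state = state, restraint = restraint,
                 bias = 0), class = "ComplexState")
}

# ---- evaluation and minimization --------------------------------------------

eval_kernel <- function(xyz, topo, spec, restraint, want_grad) {
  harm <- topo$harm
  hi <- harm$i; hj <- harm$j; hr0 <- harm$r0; hk <- harm$k
  nb_i <- topo$nb_i; nb_j <- topo$nb_j
  qq <- topo$qq; eps <- topo$eps; rmin <- topo$rmin
  if (!is.null(restraint)) {
    # the forming covalent pair is restrained, not a nonbonded contact
    drop <- (nb_i == restraint$i & nb_j == restraint$j) |
      (nb_i == restraint$j & nb_j == restraint$i)
    nb_i <- nb_i[!drop]; nb_j <- nb_j[!drop]
    qq <- qq[!drop]; eps <- eps[!drop]; rmin <- rmin[!drop]
    hi <- c(hi, restraint$i); hj <- c(hj, restraint$j)
    hr0 <- c(hr0, restraint$target); hk <- c(hk, restraint$k)
  }
  cpp_energy_gradient(xyz, as.integer(nb_i - 1L), as.integer(nb_j - 1L),
                      qq, eps, rmin,
                      as.integer(hi - 1L), as.integer(hj - 1L), hr0, hk,
                      spec$coulomb_k,
                      if (spec$dielectric == "4r") 1L else 0L,
                      spec$eps_const, want_grad)
}

#' Potential energy of a complex state
#'
#' @param state a [build_state()] result (or a plain `Structure`, treated as
#'   an unrestrained state).
#' @param spec an [energy_spec()].
#' @param topo optional precomputed [energy_topology()]; derived from the
#'   state's structure when `NULL`.
#' @return Energy in kcal/mol (arbitrary offset). Any atom pair closer than
#'   0.1 A raises an overlap error.
#' @export
evaluate_energy <- function(state, spec = energy_spec(), topo = NULL) {
  if (inherits(state, "Structure"))
    state <- structure(list(structure = state, state = "ES", restraint = NULL,
                            bias = 0), class = "ComplexState")
  if (is.null(topo)) topo <- energy_topology(state$structure, spec)
  res <- eval_kernel(state$structure$xyz, topo, spec, state$restraint, FALSE)
  if (res$min_dist < 0.1)
    stop(sprintf("overlap error: atom pair at %.3f A", res$min_dist))
  res$energy + state$bias
}

#' Minimize a complex state
#'
#' Steepest descent with step halving on energy increase; the energy trace is
#' monotone non-increasing by construction and the run is deterministic.
#'
#' @inheritParams evaluate_energy
#' @param max_iter iteration cap.
#' @param grad_tol convergence threshold on the largest per-atom gradient
#'   norm, kcal/mol/A.
#' @return A `MinimizationResult`: list with `structure`, `energy`,
#'   `initial_energy`, `iterations`, `converged`, `grad_norm`, `trace`.
#' @export
minimize_state <- function(state, spec = energy_spec(), max_iter = 2000L,
                           grad_tol = 0.01, topo = NULL) {
  if (inherits(state, "Structure"))
    state <- structure(list(structure = state, state = "ES", restraint = NULL,
                            bias = 0), class = "ComplexState")
  if (is.null(topo)) topo <- energy_topology(state$structure, spec)
  X <- state$structure$xyz
  res <- eval_kernel(X, topo, spec, state$restraint, TRUE)
  if (res$min_dist < 0.1)
    stop(sprintf("overlap error: atom pair at %.3f A", res$min_dist))
  E <- res$energy
  if (!is.finite(E)) stop("divergence error: non-finite initial energy")
  E0 <- E
  trace <- E
  step <- 1e-3
  it <- 0L
  gmax <- max(sqrt(rowSums(res$gradient^2)))
  while (it < max_iter && gmax > grad_tol) {
    it <- it + 1L
    accepted <- FALSE
    for (h in 1:40) {
      Xt <- X - step * res$gradient
      rt <- eval_kernel(Xt, topo, spec, state$restraint, TRUE)
      if (!is.finite(rt$energy)) stop("divergence error: non-finite energy")
      if (rt$energy <= E) {
        X <- Xt; E <- rt$energy; res <- rt
        step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    gmax <- max(sqrt(rowSums(res$gradient^2)))
    trace <- c(trace, E)
    if (!accepted) break
  }
  out_state <- state
  out_state$structure <- new_structure(state$structure$atoms, X,
                                       label = state$structure$label)
  structure(list(structure = out_state$structure, state = out_state,
                 energy = E + state$bias, initial_energy = E0 + state$bias,
                 iterations = it, converged = gmax <= grad_tol,
                 grad_norm = gmax, trace = trace + state$bias),
            class = "MinimizationResult")
}
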