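# Synthetic-data generators with planted ground truth: toy enzyme + substrate,
# ensembles with set per-residue flexibility, paired two-state energy tables
# with planted per-variant effects, hydrogen-bond frames at set occupancies,
# and MSAs with set per-column conservation. Every generator is deterministic
# under (config, rng_seed) and returns its GroundTruth record.

# named RNG substream: one shared seed, deterministic per generator name
substream <- function(rng_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(rng_seed) * 7919 + h * 104729) %% 2147483629)
}

subset_structure <- function(x, idx, label = x$label) {
  a <- x$atoms[idx, , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  new_structure(a, x$xyz[idx, , drop = FALSE], label = label)
}

#' Write a ground-truth sidecar as JSON
#'
#' @param gt ground-truth list returned by a generator.
#' @param path output path.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# substrate fragment in local coordinates: a 6-atom ester-like ligand
# (carbonyl C/O, ester O + methyl, alpha C, tail hydroxyl O)
substrate_local <- function() {
  xyz <- rbind(
    C1 = c(0.00, 0.00, 0.00),
    O1 = c(0.62, 1.06, 0.00),
    O2 = c(0.65, -1.15, 0.00),
    C2 = c(2.08, -1.30, 0.00),
    C3 = c(-1.50, -0.30, 0.20),
    O3 = c(-2.10, 0.40, 1.30))
  list(names = rownames(xyz), xyz = unname(xyz),
       elements = c("C", "O", "O", "C", "C", "O"))
}

#' Generate a toy enzyme with catalytic triad and bound substrate
#'
#' Builds an ideal-geometry helix-loop-helix backbone (poly-alanine) with a
#' designated Ser/His/Asp "catalytic triad" and a 6-atom ester-like substrate
#' fragment docked at the serine hydroxyl (carbonyl carbon 2.9 A from
#' Ogamma, the reactant-state pose). Loop torsions carry a small seeded
#' jitter, so coordinates are deterministic per seed. The triad residue ids,
#' substrate chain and sequence are attached as the `meta` attribute.
#'
#' @param n_res number of protein residues (>= 12).
#' @param rng_seed integer seed.
#' @return A `Structure` (protein + HETATM substrate, chain X).
#' @export
make_toy_enzyme <- function(n_res = 20L, rng_seed = 1L) {
  if (n_res < 12L)
    stop("config error: n_res must be >= 12 to host the catalytic triad")
  set.seed(substream(rng_seed, "toy_enzyme"))
  ser <- floor(n_res / 3) + 1L
  his <- floor(2L * n_res / 3) + 1L
  asp <- n_res - 1L
  seq3 <- rep("ALA", n_res)
  seq3[ser] <- "SER"; seq3[his] <- "HIS"; seq3[asp] <- "ASP"

  h1_end <- max(ser, floor(0.4 * n_res))
  loop_end <- min(his - 1L, h1_end + max(2L, floor(0.2 * n_res)))
  phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  loop <- seq(h1_end + 1L, loop_end)
  phi[loop] <- -75 + rnorm(length(loop), sd = 4)
  psi[loop] <- 145 + rnorm(length(loop), sd = 4)
  phi <- phi + rnorm(n_res, sd = 1.5)
  psi <- psi + rnorm(n_res, sd = 1.5)

  pos <- list()
  atoms <- list(); xyz <- list()
  add <- function(res, name, p, res_name, elem = substring(name, 1L, 1L)) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = 0L, name = name, element = elem, res_name = res_name,
      res_id = res, chain = "A", het = FALSE, occupancy = 1,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- p
  }
  for (i in seq_len(n_res)) {
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- CA + 1.525 * c(-cos(111.2 * pi / 180), sin(111.2 * pi / 180), 0)
    } else {
      N <- place_atom(pos$N, pos$CA, pos$C, 1.329, 116.2, psi[i - 1L])
      CA <- place_atom(pos$CA, pos$C, N, 1.458, 121.7, 180)
      C <- place_atom(pos$C, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom(N, CA, C, 1.231, 120.5, psi[i] + 180)
    add(i, "N", N, seq3[i], "N"); add(i, "CA", CA, seq3[i], "C")
    add(i, "C", C, seq3[i], "C"); add(i, "O", O, seq3[i], "O")
    tmpl <- sidechain_template(seq3[i])
    if (!is.null(tmpl)) {
      chis <- switch(seq3[i], SER = -60, HIS = c(-60, 90), ASP = c(-60, 0), 0)
      sc <- build_sidechain(list(N = N, CA = CA, C = C), tmpl, chis)
      for (k in seq_len(nrow(tmpl)))
        add(i, tmpl$name[k], sc[k, ],
            seq3[i], substring(gsub("[0-9]", "", tmpl$name[k]), 1L, 1L))
    }
    pos <- list(N = N, CA = CA, C = C)
  }
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, xyz)

  # dock the substrate at the serine hydroxyl
  og <- xyz[atoms$res_id == ser & atoms$name == "OG", ]
  ca <- xyz[atoms$res_id == ser & atoms$name == "CA", ]
  ns <- xyz[atoms$res_id == ser & atoms$name == "N", ]
  e1 <- vunit(og - ca)
  e2 <- vunit((ns - ca) - sum((ns - ca) * e1) * e1)
  e3 <- vcross(e1, e2)
  sub <- substrate_local()
  c1 <- og + 2.9 * e1
  sub_xyz <- t(apply(sub$xyz, 1L, function(v)
    c1 + v[1L] * e1 + v[2L] * e2 + v[3L] * e3))
  sub_atoms <- data.frame(serial = 0L, name = sub$names,
                          element = sub$elements, res_name = "LIG",
                          res_id = 1L, chain = "X", het = TRUE, occupancy = 1,
                          stringsAsFactors = FALSE)
  atoms <- rbind(atoms, sub_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms, rbind(xyz, sub_xyz), label = "toy_enzyme")
  attr(out, "meta") <- list(triad = c(ser, his, asp), ser = ser, his = his,
                            asp = asp, substrate_chain = "X",
                            sequence = unname(AA1_OF[seq3]),
                            rng_seed = rng_seed)
  out
}

#' Protein-only part of a structure
#'
#' @param x a `Structure`.
#' @return The structure without HETATM records (metadata preserved).
#' @export
protein_only <- function(x) {
  out <- subset_structure(x, which(!x$atoms$het), label = x$label)
  attr(out, "meta") <- attr(x, "meta")
  out
}

#' Reactant and tetrahedral-intermediate substrate templates
#'
#' Extracts the substrate fragment from a [make_toy_enzyme()] complex and
#' builds the two poses used by [build_state()]: the reactant (ES) pose as
#' docked, and the tetrahedral-intermediate (ES*) pose with the carbonyl
#' carbon moved along the Ogamma axis to the covalent-restraint target length.
#' The serine CA/CB/OG atoms are the alignment frame.
#'
#' @param toy a [make_toy_enzyme()] structure (protein + substrate).
#' @param restraint_length ES* Ogamma-carbonyl-carbon target, Angstrom.
#' @param restraint_k harmonic force constant.
#' @return List with `ES` and `ES_STAR` templates.
#' @export
make_substrate_templates <- function(toy, restraint_length = 1.9,
                                     restraint_k = 200) {
  meta <- attr(toy, "meta")
  if (is.null(meta$ser)) stop("structure lacks triad metadata")
  frag <- subset_structure(toy, which(toy$atoms$het), label = "substrate")
  ref_atoms <- data.frame(chain = "A", res_id = meta$ser,
                          name = c("CA", "CB", "OG"), stringsAsFactors = FALSE)
  ref_idx <- vapply(seq_len(3L), function(k)
    which(toy$atoms$chain == "A" & toy$atoms$res_id == meta$ser &
            toy$atoms$name == ref_atoms$name[k]), integer(1L))
  ref_coords <- toy$xyz[ref_idx, , drop = FALSE]
  og <- toy$xyz[ref_idx[3L], ]
  c1 <- frag$xyz[frag$atoms$name == "C1", ]
  shift <- (og + restraint_length * vunit(c1 - og)) - c1
  frag_star <- new_structure(frag$atoms,
                             sweep(frag$xyz, 2L, shift, "+"),
                             label = "substrate_TI")
  restraint <- list(protein = atom_spec(meta$ser, "OG", chain = "A"),
                    substrate = "C1")
  tmpl <- function(st) list(structure = st, ref_atoms = ref_atoms,
                            ref_coords = ref_coords, restraint = restraint,
                            restraint_length = restraint_length,
                            restraint_k = restraint_k)
  list(ES = tmpl(frag), ES_STAR = tmpl(frag_star))
}

#' Ensemble with controlled per-residue fluctuation
#'
#' Each frame displaces every residue rigidly by an isotropic Gaussian vector
#' with the residue's sigma, so the expected C-alpha RMSF of residue r is
#' `sigma(r) * sqrt(3)`.
#'
#' @param seed_structure a `Structure`.
#' @param per_res_sigma displacement sigma per axis (Angstrom): a single
#'   value, a vector over residues in order, or a vector named by res_id.
#'   HETATM groups get sigma 0 unless named explicitly.
#' @param n_frames number of frames (>= 2).
#' @param rng_seed integer seed.
#' @return List with `ensemble` and `ground_truth` (per-residue sigma and the
#'   expected RMSF).
#' @export
make_flex_ensemble <- function(seed_structure, per_res_sigma, n_frames = 96L,
                               rng_seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (any(per_res_sigma < 0)) stop("sigma must be non-negative")
  a <- seed_structure$atoms
  groups <- split(seq_len(nrow(a)), paste(a$chain, a$res_id))
  prot_res <- unique(a$res_id[!a$het])
  sig <- setNames(rep(0, length(groups)), names(groups))
  if (!is.null(names(per_res_sigma))) {
    for (r in names(per_res_sigma))
      sig[paste("A", r)] <- per_res_sigma[[r]]
  } else if (length(per_res_sigma) == 1L) {
    sig[paste("A", prot_res)] <- per_res_sigma
  } else {
    if (length(per_res_sigma) != length(prot_res))
      stop("per_res_sigma must match the number of protein residues")
    sig[paste("A", prot_res)] <- per_res_sigma
  }
  set.seed(substream(rng_seed, "flex_ensemble"))
  members <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- seed_structure$xyz
    for (g in seq_along(groups)) {
      if (sig[g] > 0)
        xyz[groups[[g]], ] <- sweep(xyz[groups[[g]], , drop = FALSE], 2L,
                                    rnorm(3L, sd = sig[g]), "+")
    }
    members[[f]] <- new_structure(a, xyz, label = sprintf("frame_%d", f))
  }
  gt <- list(generator = "make_flex_ensemble",
             per_res_sigma = as.list(sig[sig > 0]),
             expected_rmsf = as.list(sig[sig > 0] * sqrt(3)),
             n_frames = n_frames, rng_seed = rng_seed)
  list(ensemble = new_ensemble(members, label = "flex_ensemble"),
       ground_truth = gt)
}

delta_e_table <- function(variant, E_ES, E_ESstar, spec_id = "synthetic",
                          frameset = "synthetic") {
  df <- data.frame(variant = variant, frame = seq_along(E_ES), E_ES = E_ES,
                   E_ESstar = E_ESstar, delta_e = E_ESstar - E_ES,
                   stringsAsFactors = FALSE)
  attr(df, "energy_spec_id") <- spec_id
  attr(df, "frameset_id") <- frameset
  class(df) <- c("DeltaETable", class(df))
  df
}

#' Paired two-state energy tables with planted per-variant effects
#'
#' Wild-type per-frame energy differences are drawn from Normal(base_mean,
#' base_sd) (positive, barrier-like); each variant's frame i value is the
#' wild-type value plus its planted offset delta plus Normal(0, noise_sigma)
#' frame noise. Frames are aligned 1:1 with the wild type, mirroring the
#' ensemble-design convention.
#'
#' @param deltas named numeric vector of planted ES* offsets (kcal/mol); must
#'   include `WT = 0`.
#' @param noise_sigma frame-noise standard deviation, kcal/mol.
#' @param n_frames frames per table.
#' @param rng_seed integer seed.
#' @param base_mean,base_sd wild-type base distribution, kcal/mol.
#' @return List with `wt` (`DeltaETable`), `variants` (named list of
#'   `DeltaETable` excluding WT) and `ground_truth`.
#' @export
plant_variant_effects <- function(deltas, noise_sigma = 0.1, n_frames = 96L,
                                  rng_seed = 1L, base_mean = 10, base_sd = 1) {
  if (!"WT" %in% names(deltas))
    stop("deltas must include the wild type (WT = 0)")
  if (deltas[["WT"]] != 0) stop("wild-type delta must be 0")
  set.seed(substream(rng_seed, "plant_variant_effects"))
  base <- rnorm(n_frames, base_mean, base_sd)
  wt <- delta_e_table("WT", rep(0, n_frames), base)
  vars <- setdiff(names(deltas), "WT")
  tables <- lapply(vars, function(v) {
    de <- base + deltas[[v]] + rnorm(n_frames, 0, noise_sigma)
    delta_e_table(v, rep(0, n_frames), de)
  })
  names(tables) <- vars
  gt <- list(generator = "plant_variant_effects", deltas = as.list(deltas),
             noise_sigma = noise_sigma, n_frames = n_frames,
             base_mean = base_mean, base_sd = base_sd, rng_seed = rng_seed)
  list(wt = wt, variants = tables, ground_truth = gt)
}

#' Frames with set hydrogen-bond occupancies
#'
#' Builds a minimal donor/hydrogen/acceptor scaffold per bond and an ensemble
#' in which each bond adopts satisfying geometry (donor-acceptor 2.8 A,
#' donor-hydrogen-acceptor 165 degrees) with its target probability and
#' violating geometry (4.5 A) otherwise. `joint_mode = "independent"` draws
#' bonds independently; `"joint"` uses a single draw per frame (all bonds on
#' or off together).
#'
#' @param target_occ per-bond target occupancy, percent in \[0, 100\].
#' @param n_frames number of frames.
#' @param joint_mode `"independent"` or `"joint"`.
#' @param rng_seed integer seed.
#' @return List with `ensemble`, `defns` (matching [hbond_definition()]s) and
#'   `ground_truth` (targets and realized per-bond/all-bond frequencies).
#' @export
make_hbond_frames <- function(target_occ = c(40, 60, 80, 100), n_frames = 100L,
                              joint_mode = c("independent", "joint"),
                              rng_seed = 1L) {
  joint_mode <- match.arg(joint_mode)
  if (any(target_occ < 0 | target_occ > 100))
    stop("occupancies must be in [0, 100]")
  nb <- length(target_occ)
  p <- target_occ / 100

  # per-bond scaffold, bond sites spaced 20 A apart and staggered off-axis
  # (so C-alpha selections over several bonds are never collinear)
  base_d <- t(vapply(seq_len(nb), function(b)
    c(20 * (b - 1L), 6 * ((b - 1L) %% 2L), 0), numeric(3L)))
  mk_frame <- function(on) {
    atoms <- list(); xyz <- list()
    for (b in seq_len(nb)) {
      D <- base_d[b, ]
      CA <- D + c(-1.2, -0.8, 0.5)
      H <- D + c(1.01, 0, 0)
      if (on[b]) {
        # H->A at 165 deg from H->D, |HA| solving |DA| = 2.8 (law of cosines:
        # w^2 - 2*1.01*cos(th)*w + (1.01^2 - 2.8^2) = 0, positive root)
        th <- 165 * pi / 180
        bq <- 2 * 1.01 * cos(th)
        w <- (bq + sqrt(bq^2 - 4 * (1.01^2 - 2.8^2))) / 2
        A <- H + w * c(-cos(th), sin(th), 0)
      } else {
        A <- D + c(4.5, 0, 0)
      }
      atoms[[length(atoms) + 1L]] <- data.frame(
        serial = 0L, name = c("N", "CA", "H", "O"),
        element = c("N", "C", "H", "O"),
        res_name = c("GLY", "GLY", "GLY", "HOH"), res_id = b,
        chain = c("A", "A", "A", "X"),
        het = c(FALSE, FALSE, FALSE, TRUE), occupancy = 1,
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- rbind(D, CA, H, A)
    }
    atoms <- do.call(rbind, atoms)
    atoms$serial <- seq_len(nrow(atoms))
    new_structure(atoms, do.call(rbind, xyz), label = "hbond_frame")
  }

  set.seed(substream(rng_seed, "hbond_frames"))
  draws <- matrix(FALSE, n_frames, nb)
  for (f in seq_len(n_frames)) {
    draws[f, ] <- if (joint_mode == "joint") rep(runif(1L) < p[1L], nb)
    else runif(nb) < p
  }
  members <- lapply(seq_len(n_frames), function(f) mk_frame(draws[f, ]))
  defns <- lapply(seq_len(nb), function(b)
    hbond_definition(b, donor = atom_spec(b, "N", "A"),
                     acceptor = atom_spec(b, "O", "X"),
                     hydrogen = atom_spec(b, "H", "A"),
                     label = paste0("hbond_", b)))
  gt <- list(generator = "make_hbond_frames",
             target_occ = as.list(setNames(target_occ, paste0("hbond_", seq_len(nb)))),
             realized_occ = as.list(setNames(100 * colMeans(draws),
                                             paste0("hbond_", seq_len(nb)))),
             realized_all = 100 * mean(rowSums(draws) == nb),
             joint_mode = joint_mode, n_frames = n_frames, rng_seed = rng_seed)
  list(ensemble = new_ensemble(members, label = "hbond_frames"),
       defns = defns, ground_truth = gt)
}

#' MSA with controlled per-column conservation
#'
#' Each column has a consensus residue; every sequence carries the consensus
#' with probability equal to the column's conservation and otherwise a
#' uniform draw from the 19 other residues (so conservation 0.05 matches the
#' uniform background exactly).
#'
#' @param length alignment length.
#' @param n_seqs number of sequences (>= 2).
#' @param conservation scalar or per-column vector in \[0, 1\].
#' @param rng_seed integer seed.
#' @param consensus optional consensus sequence (1-letter string or vector);
#'   random when `NULL`.
#' @return List with `msa` and `ground_truth`.
#' @export
make_msa <- function(length, n_seqs, conservation, rng_seed = 1L,
                     consensus = NULL) {
  if (n_seqs < 2L) stop("n_seqs must be >= 2")
  if (any(conservation < 0 | conservation > 1))
    stop("conservation must be in [0, 1]")
  cons_vec <- rep_len(conservation, length)
  set.seed(substream(rng_seed, "msa"))
  if (is.null(consensus)) consensus <- sample(AA1, length, replace = TRUE)
  else if (is.character(consensus) && base::length(consensus) == 1L)
    consensus <- strsplit(toupper(consensus), "")[[1L]]
  if (base::length(consensus) != length)
    stop("consensus length must match alignment length")
  ali <- matrix("", n_seqs, length)
  for (j in seq_len(length)) {
    others <- setdiff(AA1, consensus[j])
    take <- runif(n_seqs) < cons_vec[j]
    ali[take, j] <- consensus[j]
    ali[!take, j] <- sample(others, sum(!take), replace = TRUE)
  }
  gt <- list(generator = "make_msa", conservation = as.list(cons_vec),
             consensus = paste(consensus, collapse = ""), n_seqs = n_seqs,
             rng_seed = rng_seed)
  list(msa = new_msa(ali), ground_truth = gt)
}
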