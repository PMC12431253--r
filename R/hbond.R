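# Catalytic hydrogen-bond occupancy statistics: geometric detection per frame,
# per-bond and simultaneous ("all-four") occupancy, distance-threshold scans,
# and association of occupancy with measured variant activity.

#' Atom specification
#'
#' @param res_id residue id; `name` atom name; `chain` chain id.
#' @return A list used to address one atom in a structure.
#' @export
atom_spec <- function(res_id, name, chain = "A") {
  list(chain = chain, res_id = as.integer(res_id), name = name)
}

#' Hydrogen-bond definition
#'
#' @param id numeric id (the four catalytic bonds are 1-4).
#' @param donor,acceptor [atom_spec()] of the donor and acceptor heavy atoms.
#' @param hydrogen optional [atom_spec()] of the donor hydrogen (used for the
#'   angle criterion when the atom is present in a frame).
#' @param label free-text label.
#' @return An `HBondDefinition`.
#' @export
hbond_definition <- function(id, donor, acceptor, hydrogen = NULL,
                             label = paste0("hbond_", id)) {
  if (identical(donor, acceptor)) stop("donor and acceptor must differ")
  structure(list(id = id, donor = donor, hydrogen = hydrogen,
                 acceptor = acceptor, label = label),
            class = "HBondDefinition")
}

#' The four canonical catalytic hydrogen bonds
#'
#' Bond 1: substrate carbonyl oxygen to the backbone amine of residue 16;
#' bond 2: the same oxygen to the backbone amine of residue 83 (the oxyanion
#' hole); bond 3: the catalytic serine (82) hydroxyl to the histidine (251)
#' imidazole nitrogen; bond 4: the histidine pyrrole nitrogen to the aspartate
#' (229) carboxylate. Residue numbers are configurable so the definitions
#' transfer to toy systems.
#'
#' @param oxyanion_res backbone-amine residues of bonds 1 and 2.
#' @param ser,his,asp catalytic-triad residue ids.
#' @param substrate_o substrate carbonyl-oxygen [atom_spec()].
#' @param chain protein chain.
#' @return List of four [hbond_definition()]s.
#' @export
canonical_hbonds <- function(oxyanion_res = c(16L, 83L), ser = 82L,
                             his = 251L, asp = 229L,
                             substrate_o = atom_spec(1L, "O1", chain = "X"),
                             chain = "A") {
  list(
    hbond_definition(1L, donor = atom_spec(oxyanion_res[1L], "N", chain),
                     acceptor = substrate_o, label = "carbonylO-res1N"),
    hbond_definition(2L, donor = atom_spec(oxyanion_res[2L], "N", chain),
                     acceptor = substrate_o, label = "carbonylO-res2N"),
    hbond_definition(3L, donor = atom_spec(ser, "OG", chain),
                     acceptor = atom_spec(his, "NE2", chain),
                     label = "serOG-hisNE2"),
    hbond_definition(4L, donor = atom_spec(his, "ND1", chain),
                     acceptor = atom_spec(asp, "OD2", chain),
                     label = "hisND1-aspOD2")
  )
}

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the standard geometric definition: donor-acceptor distance
#' <= 3.0 A and donor-hydrogen-acceptor angle >= 150 degrees.
#'
#' @param max_distance donor-acceptor cutoff, Angstrom.
#' @param min_angle donor-hydrogen-acceptor cutoff, degrees, in (0, 180].
#' @param fallback behaviour when the frame has no hydrogen: `"ideal_h"`
#'   places an idealized amide hydrogen when the donor is a backbone nitrogen
#'   (and falls back to distance-only otherwise); `"distance_only"` skips the
#'   angle criterion.
#' @return An `HBondCriteria`.
#' @export
hbond_criteria <- function(max_distance = 3.0, min_angle = 150,
                           fallback = c("ideal_h", "distance_only")) {
  if (max_distance <= 0) stop("max_distance must be positive")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 fallback = match.arg(fallback)), class = "HBondCriteria")
}

find_atom <- function(x, spec, what = "atom") {
  hit <- which(x$atoms$chain == spec$chain & x$atoms$res_id == spec$res_id &
                 x$atoms$name == spec$name)
  if (length(hit) != 1L)
    stop("definition error: ", what, " ", spec$chain, "/", spec$res_id, "/",
         spec$name, " not found")
  hit
}

ideal_amide_h <- function(x, donor_idx) {
  a <- x$atoms
  if (a$name[donor_idx] != "N") return(NULL)
  rid <- a$res_id[donor_idx]; ch <- a$chain[donor_idx]
  ca <- which(a$chain == ch & a$res_id == rid & a$name == "CA")
  cp <- which(a$chain == ch & a$res_id == rid - 1L & a$name == "C")
  if (length(ca) != 1L || length(cp) != 1L) return(NULL)
  n <- x$xyz[donor_idx, ]
  dir <- n - (x$xyz[ca, ] + x$xyz[cp, ]) / 2
  n + 1.01 * vunit(dir)
}

#' Detect a hydrogen bond in one frame
#'
#' True iff the donor-acceptor distance is within the cutoff and, when a
#' hydrogen position is available (explicit or idealized), the
#' donor-hydrogen-acceptor angle meets the cutoff.
#'
#' @param frame a `Structure`.
#' @param defn an [hbond_definition()].
#' @param crit an [hbond_criteria()].
#' @return Logical scalar.
#' @export
detect_hbond <- function(frame, defn, crit = hbond_criteria()) {
  di <- find_atom(frame, defn$donor, "donor")
  ai <- find_atom(frame, defn$acceptor, "acceptor")
  d <- frame$xyz[di, ]; a <- frame$xyz[ai, ]
  if (vnorm(d - a) > crit$max_distance) return(FALSE)
  h <- NULL
  if (!is.null(defn$hydrogen)) {
    hit <- which(frame$atoms$chain == defn$hydrogen$chain &
                   frame$atoms$res_id == defn$hydrogen$res_id &
                   frame$atoms$name == defn$hydrogen$name)
    if (length(hit) == 1L) h <- frame$xyz[hit, ]
  }
  if (is.null(h) && crit$fallback == "ideal_h") h <- ideal_amide_h(frame, di)
  if (is.null(h)) return(TRUE) # distance-only
  atom_angle(d, h, a) >= crit$min_angle
}

#' Hydrogen-bond occupancy over an ensemble of frames
#'
#' Per-bond formation frequency (percent of frames satisfying the criteria)
#' plus the simultaneous all-bonds frequency (the transition-state-analogue
#' metric), which is never larger than any individual frequency.
#'
#' @param frames an `Ensemble`.
#' @param defns list of [hbond_definition()]s.
#' @param crit an [hbond_criteria()].
#' @return Data.frame with columns `bond` (labels plus `"all"`),
#'   `frequency_pct`, `n_frames`.
#' @export
hbond_occupancy <- function(frames, defns, crit = hbond_criteria()) {
  if (!inherits(frames, "Ensemble") || length(frames$members) < 1L)
    stop("insufficient frames: need an Ensemble with >= 1 member")
  nf <- length(frames$members)
  hits <- matrix(FALSE, nf, length(defns))
  for (k in seq_len(nf)) for (b in seq_along(defns))
    hits[k, b] <- detect_hbond(frames$members[[k]], defns[[b]], crit)
  labels <- vapply(defns, function(d) d$label, character(1L))
  data.frame(
    bond = c(labels, "all"),
    frequency_pct = 100 * c(colMeans(hits), mean(rowSums(hits) == length(defns))),
    n_frames = nf, stringsAsFactors = FALSE)
}

#' Occupancy under a series of distance thresholds
#'
#' Recomputes [hbond_occupancy()] at each donor-acceptor cutoff (the protocol
#' scans 2.5-4.0 A). In distance-only mode the frequencies are monotone
#' non-decreasing in the threshold.
#'
#' @param frames an `Ensemble`.
#' @param defns list of [hbond_definition()]s.
#' @param distances ascending vector of cutoffs, Angstrom.
#' @param crit base criteria; the distance is replaced per scan point.
#' @return Data.frame of occupancy tables stacked with a `max_distance`
#'   column.
#' @export
threshold_scan <- function(frames, defns, distances = c(2.5, 3.0, 3.5, 4.0),
                           crit = hbond_criteria(fallback = "distance_only")) {
  if (is.unsorted(distances, strictly = TRUE))
    stop("input error: distances must be sorted ascending")
  out <- lapply(distances, function(d) {
    ci <- crit; ci$max_distance <- d
    cbind(max_distance = d, hbond_occupancy(frames, defns, ci))
  })
  do.call(rbind, out)
}

# ---- activity association ---------------------------------------------------

#' Packaged variant-activity fixture
#'
#' Relative hydrolytic activities of the wild type and engineered lipase
#' variants toward the Roche ester and p-nitrophenyl butyrate, as percentages
#' normalized to wild type (100). Missing p-NPB entries are NA.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return Data.frame with columns `variant`, `roche_activity_pct`,
#'   `pnpb_activity_pct`.
#' @export
load_activity_table <- function(path = system.file("extdata",
                                                   "lipa_activity_table1.tsv",
                                                   package = "ensdesign")) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", "Na"))
  if (!"WT" %in% df$variant) stop("activity table must contain the wild type")
  if (any(df$roche_activity_pct < 0, na.rm = TRUE))
    stop("activities must be non-negative")
  df
}

spearman_perm <- function(x, y, n_perm) {
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = 0, p = NA_real_, degenerate = TRUE))
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  perm_rho <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)),
                     numeric(1L))
  p <- (1 + sum(abs(perm_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Association between hydrogen-bond occupancy and variant activity
#'
#' Per (reaction step, bond): Spearman correlation of occupancy with relative
#' activity (average-rank tie handling; zero-variance series reported as
#' rho = 0 with a degeneracy flag) with a seeded permutation p-value, plus a
#' rank-sum (Wilcoxon) comparison of occupancies between active and inactive
#' variants (inactive = activity exactly 0). Raw p-values are reported
#' alongside Benjamini-Hochberg adjusted ones.
#'
#' @param occ tidy occupancy table: columns `variant`, `step`, `bond`,
#'   `frequency_pct`.
#' @param act activity table: columns `variant` and `activity` (or
#'   `roche_activity_pct`).
#' @param n_perm permutations for the Spearman p-value.
#' @param rng_seed integer seed.
#' @return Data.frame per (step, bond): `rho`, `p_perm`, `p_perm_bh`,
#'   `rank_sum_p`, `rank_sum_p_bh`, `degenerate`, `group_flag`, `n`.
#' @export
activity_association <- function(occ, act, n_perm = 10000L, rng_seed = 1L) {
  if (is.null(act$activity)) act$activity <- act$roche_activity_pct
  shared <- intersect(unique(occ$variant), act$variant)
  if (length(shared) < 4L)
    stop("need >= 4 variants shared between occupancy and activity tables")
  occ <- occ[occ$variant %in% shared, , drop = FALSE]
  act <- act[match(shared, act$variant), c("variant", "activity")]
  set.seed(rng_seed)
  cells <- unique(occ[, c("step", "bond")])
  res <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sub <- occ[occ$step == cells$step[k] & occ$bond == cells$bond[k], ]
    sub <- sub[match(shared, sub$variant), ]
    y <- act$activity
    x <- sub$frequency_pct
    sp <- spearman_perm(x, y, n_perm)
    inactive <- y == 0
    group_flag <- ""
    rsp <- NA_real_
    if (sum(inactive) < 2L || sum(!inactive) < 2L) {
      group_flag <- "group-size error: <2 variants in a group"
    } else if (sd(x) == 0) {
      group_flag <- "degenerate: constant occupancy"
    } else {
      rsp <- suppressWarnings(
        wilcox.test(x[!inactive], x[inactive], exact = FALSE)$p.value)
    }
    res[[k]] <- data.frame(step = cells$step[k], bond = cells$bond[k],
                           rho = sp$rho, p_perm = sp$p,
                           rank_sum_p = rsp, degenerate = sp$degenerate,
                           group_flag = group_flag, n = length(shared),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_perm_bh <- p.adjust(out$p_perm, method = "BH")
  out$rank_sum_p_bh <- p.adjust(out$rank_sum_p, method = "BH")
  out
}
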