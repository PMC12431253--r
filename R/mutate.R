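# In-silico point mutagenesis: side-chain rebuild from ideal-geometry rotamer
# templates with a minimal chi-grid clash search, plus variant enumeration.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
names(AA3) <- AA1
AA1_OF <- setNames(AA1, AA3)

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

# van der Waals radii (Bondi), Angstrom
vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Side-chain template rows: atom placed from frame a-b-c with given bond
# length and angle; `chi` > 0 means the dihedral is chi_k + offset, otherwise
# the dihedral is fixed at `offset`. Rings are approximated by fixed planar
# internal coordinates (a deliberately low-fidelity stand-in for a rotamer
# library: geometry is ideal, chi sampling is a coarse grid).
tmpl_row <- function(name, a, b, c, bond, angle, chi, offset) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = chi, offset = offset, stringsAsFactors = FALSE)
}

sidechain_template <- function(res3) {
  cb <- tmpl_row("CB", "N", "C", "CA", 1.53, 110.6, 0L, 122.6)
  g1 <- function(name, bond, angle) tmpl_row(name, "N", "CA", "CB", bond, angle, 1L, 0)
  g2 <- function(name, bond, angle, off = 0) tmpl_row(name, "CA", "CB", "CG", bond, angle, 2L, off)
  rows <- switch(res3,
    GLY = NULL,
    ALA = cb,
    SER = rbind(cb, g1("OG", 1.42, 110.8)),
    CYS = rbind(cb, g1("SG", 1.81, 113.8)),
    THR = rbind(cb, g1("OG1", 1.43, 109.5),
                tmpl_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, -120)),
    VAL = rbind(cb, g1("CG1", 1.52, 110.5),
                tmpl_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, 122)),
    LEU = rbind(cb, g1("CG", 1.53, 116.3), g2("CD1", 1.52, 110.5),
                g2("CD2", 1.52, 110.5, 122)),
    ILE = rbind(cb, g1("CG1", 1.53, 110.4),
                tmpl_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1L, -122),
                tmpl_row("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2L, 0)),
    MET = rbind(cb, g1("CG", 1.52, 114.1), g2("SD", 1.81, 112.7),
                tmpl_row("CE", "CB", "CG", "SD", 1.79, 100.9, 3L, 0)),
    PRO = rbind(cb, tmpl_row("CG", "N", "CA", "CB", 1.50, 104.5, 0L, 30),
                tmpl_row("CD", "CA", "CB", "CG", 1.51, 106.1, 0L, -35)),
    PHE = rbind(cb, g1("CG", 1.50, 113.8), g2("CD1", 1.39, 120.8),
                g2("CD2", 1.39, 120.8, 180),
                tmpl_row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
                tmpl_row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
                tmpl_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0)),
    TYR = rbind(cb, g1("CG", 1.50, 113.8), g2("CD1", 1.39, 120.8),
                g2("CD2", 1.39, 120.8, 180),
                tmpl_row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0L, 180),
                tmpl_row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0L, 180),
                tmpl_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0L, 0),
                tmpl_row("OH", "CD1", "CE1", "CZ", 1.38, 119.9, 0L, 180)),
    TRP = rbind(cb, g1("CG", 1.50, 113.6), g2("CD1", 1.37, 126.9),
                g2("CD2", 1.43, 126.7, 180),
                tmpl_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0L, 180),
                tmpl_row("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0L, 180),
                tmpl_row("CE3", "CD1", "CG", "CD2", 1.40, 133.9, 0L, 180),
                tmpl_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0L, 180),
                tmpl_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 0L, 180),
                tmpl_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0L, 0)),
    HIS = rbind(cb, g1("CG", 1.50, 113.8), g2("ND1", 1.38, 122.7),
                g2("CD2", 1.36, 131.1, 180),
                tmpl_row("CE1", "CB", "CG", "ND1", 1.32, 109.2, 0L, 180),
                tmpl_row("NE2", "CB", "CG", "CD2", 1.37, 107.2, 0L, 180)),
    ASP = rbind(cb, g1("CG", 1.52, 113.1), g2("OD1", 1.25, 118.2),
                g2("OD2", 1.25, 118.2, 180)),
    ASN = rbind(cb, g1("CG", 1.52, 112.7), g2("OD1", 1.23, 120.9),
                g2("ND2", 1.33, 116.5, 180)),
    GLU = rbind(cb, g1("CG", 1.53, 114.1), g2("CD", 1.52, 112.6),
                tmpl_row("OE1", "CB", "CG", "CD", 1.25, 118.3, 3L, 0),
                tmpl_row("OE2", "CB", "CG", "CD", 1.25, 118.3, 3L, 180)),
    GLN = rbind(cb, g1("CG", 1.53, 114.1), g2("CD", 1.52, 112.6),
                tmpl_row("OE1", "CB", "CG", "CD", 1.23, 120.9, 3L, 0),
                tmpl_row("NE2", "CB", "CG", "CD", 1.33, 116.5, 3L, 180)),
    LYS = rbind(cb, g1("CG", 1.53, 114.1), g2("CD", 1.52, 111.3),
                tmpl_row("CE", "CB", "CG", "CD", 1.52, 111.3, 3L, 0),
                tmpl_row("NZ", "CG", "CD", "CE", 1.49, 111.9, 4L, 0)),
    ARG = rbind(cb, g1("CG", 1.53, 114.1), g2("CD", 1.52, 111.3),
                tmpl_row("NE", "CB", "CG", "CD", 1.46, 112.0, 3L, 0),
                tmpl_row("CZ", "CG", "CD", "NE", 1.33, 124.2, 4L, 0),
                tmpl_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0L, 0),
                tmpl_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0L, 180)),
    stop("no side-chain template for residue type ", res3)
  )
  rows
}

n_chi <- function(tmpl) if (is.null(tmpl)) 0L else max(tmpl$chi, 0L)

# place all template atoms given the backbone frame positions (list with
# N/CA/C) and a chi-angle vector; returns the side-chain coordinate matrix
build_sidechain <- function(pos, tmpl, chis) {
  out <- matrix(0, nrow = if (is.null(tmpl)) 0L else nrow(tmpl), ncol = 3L)
  if (is.null(tmpl)) return(out)
  for (k in seq_len(nrow(tmpl))) {
    r <- tmpl[k, ]
    dih <- if (r$chi > 0L) chis[r$chi] + r$offset else r$offset
    p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, dih)
    pos[[r$name]] <- p
    out[k, ] <- p
  }
  out
}

# ---- mutation specs ---------------------------------------------------------

#' Point-mutation specifications
#'
#' `mutation_spec()` builds a single-substitution spec; `parse_variant()`
#' parses canonical variant names such as `"H14G"` or `"H14G_L17A"` (double
#' mutants joined by `_`); `variant_name()` is its inverse.
#'
#' @param chain chain id.
#' @param res_id residue number.
#' @param from,to 1-letter amino-acid codes; `to` must differ from `from`.
#' @return `mutation_spec()`: a `MutationSpec`; `parse_variant()`: a list of
#'   `MutationSpec` (one per substitution); `variant_name()`: the canonical
#'   name string.
#' @export
mutation_spec <- function(res_id, from, to, chain = "A") {
  from <- toupper(from); to <- toupper(to)
  if (!from %in% AA1 || !to %in% AA1) stop("unknown amino-acid code")
  if (from == to) stop("spec error: to_aa must differ from from_aa")
  structure(list(chain = chain, res_id = as.integer(res_id),
                 from = from, to = to), class = "MutationSpec")
}

#' @rdname mutation_spec
#' @param name canonical variant name, e.g. `"H14G_L17A"`.
#' @export
parse_variant <- function(name, chain = "A") {
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Z])([0-9]+)([A-Z])$", p))[[1L]]
    if (length(m) != 4L) stop("unparseable mutation name: ", p)
    mutation_spec(as.integer(m[3L]), m[2L], m[4L], chain = chain)
  })
}

#' @rdname mutation_spec
#' @param specs a `MutationSpec` or list of them.
#' @export
variant_name <- function(specs) {
  if (inherits(specs, "MutationSpec")) specs <- list(specs)
  specs <- specs[order(vapply(specs, function(s) s$res_id, integer(1L)),
                       vapply(specs, function(s) s$chain, character(1L)))]
  paste(vapply(specs, function(s) paste0(s$from, s$res_id, s$to),
               character(1L)), collapse = "_")
}

# ---- application ------------------------------------------------------------

clash_count <- function(new_xyz, new_elem, env_xyz, env_elem, factor = 0.8) {
  if (nrow(new_xyz) == 0L || nrow(env_xyz) == 0L) return(0L)
  rn <- vdw_radius[toupper(new_elem)]; rn[is.na(rn)] <- 1.7
  re <- vdw_radius[toupper(env_elem)]; re[is.na(re)] <- 1.7
  cnt <- 0L
  for (k in seq_len(nrow(new_xyz))) {
    d <- sqrt(colSums((t(env_xyz) - new_xyz[k, ])^2))
    cnt <- cnt + sum(d < factor * (rn[k] + re))
  }
  cnt
}

#' Apply a point mutation to a structure
#'
#' Backbone atoms (N, CA, C, O) are untouched; the side chain is rebuilt from
#' an ideal-geometry template, with chi angles searched over a coarse grid
#' (default -60/60/180 degrees per rotatable bond) and the combination with
#' the lowest steric clash count selected (ties broken by first-encountered
#' grid order, so results are deterministic). Clashes are heavy-atom pairs
#' closer than `clash_factor` times the sum of van der Waals radii against all
#' atoms outside the mutated residue and its chain neighbours.
#'
#' @param x a `Structure`.
#' @param spec a [mutation_spec()] (or a name parseable by [parse_variant()]
#'   containing a single substitution).
#' @param clash_cfg list: `factor` (default 0.8), `chi_grid` (default
#'   `c(-60, 60, 180)`), `max_clashes` (default 0; exceeding it flags the
#'   output with a `clash_warning` attribute and a warning).
#' @return The mutated `Structure`; attribute `clash_warning` is `TRUE` when
#'   no rotamer at or below `max_clashes` exists.
#' @export
apply_mutation <- function(x, spec, clash_cfg = list()) {
  if (is.character(spec)) {
    sp <- parse_variant(spec)
    if (length(sp) != 1L) stop("apply_mutation takes a single substitution")
    spec <- sp[[1L]]
  }
  cfg <- merge_config(list(factor = 0.8, chi_grid = c(-60, 60, 180),
                           max_clashes = 0L), clash_cfg)
  a <- x$atoms
  rid <- which(a$chain == spec$chain & a$res_id == spec$res_id & !a$het)
  if (!length(rid)) stop("spec error: residue ", spec$res_id, " not found")
  present <- unique(a$res_name[rid])
  if (length(present) != 1L || AA1_OF[present] != spec$from)
    stop("spec error: residue ", spec$res_id, " is ", present,
         ", not ", AA3[spec$from])

  bb_idx <- rid[a$name[rid] %in% BACKBONE_NAMES]
  if (!all(c("N", "CA", "C") %in% a$name[bb_idx]))
    stop("residue ", spec$res_id, " lacks backbone atoms")
  frame <- function(nm) x$xyz[bb_idx[match(nm, a$name[bb_idx])], ]
  tmpl <- sidechain_template(AA3[spec$to])

  env_idx <- which(!(a$res_id %in% (spec$res_id + (-1L:1L)) &
                       a$chain == spec$chain & !a$het))
  env_xyz <- x$xyz[env_idx, , drop = FALSE]
  env_elem <- a$element[env_idx]

  bb_pos <- list(N = frame("N"), CA = frame("CA"), C = frame("C"))
  nch <- n_chi(tmpl)
  best <- NULL; best_clash <- Inf
  combos <- if (nch == 0L) matrix(0, 1L, 0L) else
    as.matrix(rev(expand.grid(rev(rep(list(cfg$chi_grid), nch)))))
  elem_new <- if (is.null(tmpl)) character(0) else
    substring(gsub("[0-9]", "", tmpl$name), 1L, 1L)
  for (ci in seq_len(nrow(combos))) {
    xyz_new <- build_sidechain(bb_pos, tmpl, as.numeric(combos[ci, ]))
    cl <- clash_count(xyz_new, elem_new, env_xyz, env_elem, cfg$factor)
    if (cl < best_clash) { best_clash <- cl; best <- xyz_new }
    if (best_clash == 0L) break
  }

  # assemble: backbone rows (original order/coords), then template side chain
  keep_order <- bb_idx[order(match(a$name[bb_idx], BACKBONE_NAMES))]
  res_rows <- data.frame(
    serial = 0L,
    name = c(a$name[keep_order], if (is.null(tmpl)) character(0) else tmpl$name),
    element = c(a$element[keep_order], elem_new),
    res_name = unname(AA3[spec$to]),
    res_id = spec$res_id, chain = spec$chain,
    het = FALSE, occupancy = 1, stringsAsFactors = FALSE
  )
  res_xyz <- rbind(x$xyz[keep_order, , drop = FALSE], best)

  before <- seq_len(nrow(a)) < min(rid)
  after <- seq_len(nrow(a)) > max(rid)
  atoms <- rbind(a[before, , drop = FALSE], res_rows, a[after, , drop = FALSE])
  xyz <- rbind(x$xyz[before, , drop = FALSE], res_xyz,
               x$xyz[after, , drop = FALSE])
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms, xyz,
                       label = paste0(x$label, "|", variant_name(spec)))
  if (best_clash > cfg$max_clashes) {
    warning(variant_name(spec), ": best rotamer keeps ", best_clash,
            " clash(es)")
    attr(out, "clash_warning") <- TRUE
  }
  out
}

#' Apply a (possibly multi-substitution) variant
#'
#' @param x a `Structure` or `Ensemble` (applied member-wise).
#' @param specs a variant name, a `MutationSpec`, or a list of `MutationSpec`.
#' @param clash_cfg see [apply_mutation()].
#' @return Mutated object of the same class as `x`.
#' @export
apply_variant <- function(x, specs, clash_cfg = list()) {
  if (is.character(specs)) specs <- parse_variant(specs)
  if (inherits(specs, "MutationSpec")) specs <- list(specs)
  if (inherits(x, "Ensemble")) {
    members <- lapply(x$members, apply_variant, specs = specs,
                      clash_cfg = clash_cfg)
    return(new_ensemble(members, label = paste0(x$label, "|",
                                                variant_name(specs))))
  }
  for (sp in specs) x <- apply_mutation(x, sp, clash_cfg)
  x
}

# ---- enumeration ------------------------------------------------------------

residue_aa <- function(x, res_id, chain = "A") {
  rn <- unique(x$atoms$res_name[x$atoms$res_id == res_id &
                                  x$atoms$chain == chain & !x$atoms$het])
  if (length(rn) != 1L) stop("residue ", res_id, " not found in chain ", chain)
  unname(AA1_OF[rn])
}

#' Enumerate single-point mutations
#'
#' For each position, all 19 substitutions away from the present residue,
#' minus excluded target residues; ordering is stable (position, then
#' alphabetical target).
#'
#' @param x a `Structure`.
#' @param positions residue ids to mutate; default all protein residues.
#' @param excluded 1-letter codes never used as targets.
#' @param chain chain id.
#' @return List of `MutationSpec`.
#' @export
enumerate_singles <- function(x, positions = NULL, excluded = character(0),
                              chain = "A") {
  if (is.null(positions))
    positions <- sort(unique(x$atoms$res_id[x$atoms$chain == chain & !x$atoms$het]))
  if (!length(positions)) return(list())
  out <- list()
  for (p in positions) {
    from <- residue_aa(x, p, chain)
    for (to in sort(setdiff(AA1, c(from, toupper(excluded)))))
      out[[length(out) + 1L]] <- mutation_spec(p, from, to, chain)
  }
  out
}

#' Enumerate double mutants from template variants
#'
#' Cross product of template single mutations with all single substitutions at
#' the candidate positions; template and candidate positions must be disjoint.
#'
#' @param template_specs list of `MutationSpec` used as fixed first
#'   substitutions (e.g. the top single-point variants).
#' @inheritParams enumerate_singles
#' @return List of variants, each a list of two `MutationSpec`, canonically
#'   named via [variant_name()] with no duplicates.
#' @export
enumerate_doubles <- function(template_specs, x, positions,
                              excluded = character(0), chain = "A") {
  tpos <- vapply(template_specs, function(s) s$res_id, integer(1L))
  if (length(intersect(tpos, positions)))
    stop("spec error: template and candidate positions overlap")
  singles <- enumerate_singles(x, positions, excluded, chain)
  out <- list()
  for (t in template_specs) for (s in singles)
    out[[length(out) + 1L]] <- list(t, s)
  nms <- vapply(out, variant_name, character(1L))
  out[!duplicated(nms)]
}
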