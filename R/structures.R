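#' @useDynLib ensdesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd cor wilcox.test p.adjust ks.test setNames
#' @importFrom utils read.table write.table
NULL

# ---- constructors -----------------------------------------------------------

#' Create a molecular structure
#'
#' A `Structure` holds an ordered atom table and an n x 3 coordinate matrix in
#' Angstrom. Atom identity is the triple (chain, res_id, name), which must be
#' unique within a structure.
#'
#' @param atoms data.frame with columns `serial` (integer), `name`, `element`,
#'   `res_name` (3-letter code), `res_id` (integer, 1-based as in PDB),
#'   `chain` (single character), and optionally `het` (logical, HETATM flag)
#'   and `occupancy`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param label free-text label.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, xyz, label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) < 1L) stop("a Structure needs at least one atom")
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix matching the atom table")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  atoms$res_id <- as.integer(atoms$res_id)
  atoms$serial <- as.integer(atoms$serial)
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("malformed input: duplicate atom ", key[duplicated(key)][1L],
         " (chain/res_id/name must be unique)")
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, label = label),
            class = "Structure")
}

atom_key <- function(atoms) paste(atoms$chain, atoms$res_id, atoms$name, sep = "/")

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure '%s': %d atoms, %d residues\n", x$label,
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$res_id)))))
  invisible(x)
}

#' Create an ensemble of topology-identical structures
#'
#' All members must share the same atoms (names, residues, order); only the
#' coordinates differ between members.
#'
#' @param members list of [new_structure()] objects.
#' @param label free-text label.
#' @return An object of class `Ensemble`.
#' @export
new_ensemble <- function(members, label = "") {
  if (length(members) < 1L) stop("an Ensemble needs at least one member")
  ref <- atom_key(members[[1L]]$atoms)
  for (k in seq_along(members)) {
    if (!identical(atom_key(members[[k]]$atoms), ref))
      stop("topology error: member ", k,
           " does not share the atom set/order of member 1")
  }
  structure(list(members = members, label = label), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d members x %d atoms\n", x$label,
              length(x$members), nrow(x$members[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.Ensemble <- function(x) length(x$members)

# coordinates of all members as an n_atoms x 3 x n_members array
ensemble_coords <- function(ensemble) {
  n <- nrow(ensemble$members[[1L]]$xyz)
  arr <- array(0, dim = c(n, 3L, length(ensemble$members)))
  for (k in seq_along(ensemble$members)) arr[, , k] <- ensemble$members[[k]]$xyz
  arr
}

# ---- PDB I/O ----------------------------------------------------------------

pdb_field <- function(lines, from, to) trimws(substring(lines, from, to))

guess_element <- function(name) {
  e <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name))
  e <- substring(e, 1L, 1L)
  toupper(e)
}

#' Read a (multi-model) PDB structure
#'
#' Parses ATOM/HETATM records with optional MODEL/ENDMDL blocks into an
#' [new_ensemble()] (a single-member ensemble when no MODEL records are
#' present). Coordinates are taken at the printed PDB precision (0.001 A).
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer, ties broken by altloc letter order.
#'
#' @param pdb_text PDB text: a single string, a character vector of lines, or
#'   a path to an existing file.
#' @param label label for the returned ensemble.
#' @return An `Ensemble`; duplicate atoms within a model raise a
#'   malformed-input error and differing atom sets across models raise a
#'   topology error.
#' @export
read_structure <- function(pdb_text, label = "") {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text))
    pdb_text <- readLines(pdb_text)
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  rec <- substring(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("malformed input: no ATOM/HETATM records")
  is_model_open <- startsWith(lines, "MODEL")
  model_id <- cumsum(is_model_open)
  model_id[model_id == 0L] <- 1L
  model_of_atom <- model_id[is_atom]
  al <- lines[is_atom]

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(pdb_field(al, 7, 11))),
    name = pdb_field(al, 13, 16),
    altloc = substring(al, 17, 17),
    res_name = pdb_field(al, 18, 20),
    chain = substring(al, 22, 22),
    res_id = suppressWarnings(as.integer(pdb_field(al, 23, 26))),
    occupancy = suppressWarnings(as.numeric(pdb_field(al, 55, 60))),
    element = pdb_field(al, 77, 78),
    het = rec[is_atom] == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  miss <- atoms$element == "" | is.na(atoms$element)
  atoms$element[miss] <- guess_element(atoms$name[miss])
  xyz <- cbind(
    as.numeric(substring(al, 31, 38)),
    as.numeric(substring(al, 39, 46)),
    as.numeric(substring(al, 47, 54))
  )
  if (any(!is.finite(xyz))) stop("malformed input: unreadable coordinates")

  members <- lapply(split(seq_len(nrow(atoms)), model_of_atom), function(idx) {
    a <- atoms[idx, , drop = FALSE]
    x <- xyz[idx, , drop = FALSE]
    # altloc policy: keep highest occupancy, ties by altloc letter order
    key <- paste(a$chain, a$res_id, a$name, sep = "/")
    if (anyDuplicated(key)) {
      keep <- logical(nrow(a))
      for (g in split(seq_len(nrow(a)), key)) {
        if (length(g) > 1L && all(a$altloc[g] != " ") &&
            !anyDuplicated(a$altloc[g])) {
          ord <- order(-a$occupancy[g], a$altloc[g])
          keep[g[ord[1L]]] <- TRUE
        } else if (length(g) > 1L) {
          stop("malformed input: duplicate atom ", key[g[1L]], " within a model")
        } else keep[g] <- TRUE
      }
      a <- a[keep, , drop = FALSE]
      x <- x[keep, , drop = FALSE]
    }
    a$altloc <- NULL
    new_structure(a, x, label = label)
  })
  names(members) <- NULL
  new_ensemble(members, label = label)
}

#' Write an ensemble as multi-model PDB text
#'
#' Inverse of [read_structure()]: names, residue ids and coordinates
#' round-trip at 0.001 A. Single-member ensembles are written without
#' MODEL/ENDMDL wrappers.
#'
#' @param ensemble an `Ensemble` or a single `Structure`.
#' @param path optional file path; when given the text is also written there.
#' @return The PDB text as a character vector of lines (invisibly when `path`
#'   is given).
#' @export
write_structure <- function(ensemble, path = NULL) {
  if (inherits(ensemble, "Structure")) ensemble <- new_ensemble(list(ensemble))
  if (!inherits(ensemble, "Ensemble")) stop("expected an Ensemble or Structure")
  multi <- length(ensemble$members) > 1L
  out <- character(0)
  for (k in seq_along(ensemble$members)) {
    s <- ensemble$members[[k]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    nm <- ifelse(nchar(s$atoms$name) < 4L, paste0(" ", s$atoms$name), s$atoms$name)
    out <- c(out, sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(s$atoms$het, "HETATM", "ATOM"),
      s$atoms$serial, nm, s$atoms$res_name, s$atoms$chain, s$atoms$res_id,
      s$xyz[, 1L], s$xyz[, 2L], s$xyz[, 3L], s$atoms$occupancy, 0,
      s$atoms$element))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- selections -------------------------------------------------------------

#' Atom selections
#'
#' A `Selection` restricts operations (superposition, RMSD, RMSF) to a subset
#' of atoms identified by chain, residue id and/or atom name. Applying a
#' selection to topology-identical structures yields index-identical subsets.
#'
#' `selection_ca()` selects all C-alpha atoms; `selection_backbone()` selects
#' N/CA/C/O of the given residues (the active-site backbone selection of the
#' design protocol uses residues 16, 82, 83, 229 and 251).
#'
#' @param chain,res_id,atom_names optional vectors; `NULL` means no
#'   restriction on that field.
#' @param label selection label.
#' @return An object of class `Selection`.
#' @export
selection <- function(chain = NULL, res_id = NULL, atom_names = NULL,
                      label = "custom") {
  structure(list(chain = chain, res_id = if (is.null(res_id)) NULL else
    as.integer(res_id), atom_names = atom_names, label = label),
    class = "Selection")
}

#' @rdname selection
#' @export
selection_ca <- function() selection(atom_names = "CA", label = "CA")

#' @rdname selection
#' @param res_ids residues whose backbone atoms are selected.
#' @export
selection_backbone <- function(res_ids = c(16L, 82L, 83L, 229L, 251L)) {
  selection(res_id = res_ids, atom_names = c("N", "CA", "C", "O"),
            label = "active_site_backbone")
}

#' Indices of atoms matched by a selection
#'
#' @param x a `Structure`.
#' @param sel a [selection()].
#' @return Integer vector of atom indices (in structure order).
#' @export
select_atoms <- function(x, sel) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$res_id)) keep <- keep & a$res_id %in% sel$res_id
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  which(keep)
}
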