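# Position-specific scoring matrix for the evolutionary-conservation filter.

#' Multiple sequence alignment container
#'
#' @param sequences character vector of aligned sequences (equal length,
#'   20 amino acids plus `-` gaps), or a character matrix (one row per
#'   sequence).
#' @param ids sequence identifiers.
#' @return An `MSA`: list with `ali` (character matrix, rows = sequences) and
#'   `ids`.
#' @export
new_msa <- function(sequences, ids = NULL) {
  if (is.matrix(sequences)) ali <- sequences
  else {
    if (length(unique(nchar(sequences))) != 1L)
      stop("aligned sequences must have uniform length")
    ali <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  if (nrow(ali) < 2L) stop("an MSA needs at least 2 sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(ali)))
  rownames(ali) <- ids
  structure(list(ali = ali, ids = ids), class = "MSA")
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over [bio3d::read.fasta()] / [bio3d::write.fasta()].
#'
#' @param path file path.
#' @return `read_msa()`: an [new_msa()] object.
#' @export
read_msa <- function(path) {
  fa <- bio3d::read.fasta(path)
  new_msa(toupper(fa$ali), ids = fa$id)
}

#' @rdname read_msa
#' @param msa an `MSA`.
#' @export
write_msa <- function(msa, path) {
  bio3d::write.fasta(seqs = msa$ali, ids = msa$ids, file = path)
  invisible(path)
}

#' Compute a position-specific scoring matrix
#'
#' Log-odds (base 2) of pseudocount-smoothed column frequencies against a
#' background distribution:
#' `score(p, a) = log2((count(p,a) + pc * bg(a)) / ((N_eff(p) + pc) * bg(a)))`
#' where `N_eff(p)` is the non-gap count at position `p`; gaps are excluded
#' from counts. All-gap columns are scored from pseudocounts alone and
#' flagged.
#'
#' @param msa an [new_msa()].
#' @param background named length-20 probability vector (default uniform);
#'   must be strictly positive and sum to 1.
#' @param pseudocount positive pseudocount weight (default 1, scaled by the
#'   background).
#' @return A `PSSMMatrix`: list with `scores` (positions x 20, bits),
#'   `background`, `pseudocount`, `n_eff`, `all_gap`.
#' @export
compute_pssm <- function(msa, background = NULL, pseudocount = 1) {
  if (is.null(background)) background <- setNames(rep(1 / 20, 20L), AA1)
  background <- background[AA1]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be a strictly positive distribution over the 20 aa")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  ali <- msa$ali
  L <- ncol(ali)
  counts <- matrix(0, L, 20L, dimnames = list(NULL, AA1))
  for (a in AA1) counts[, a] <- colSums(ali == a)
  n_eff <- rowSums(counts)
  num <- sweep(counts, 2L, pseudocount * background, "+")
  den <- (n_eff + pseudocount)
  scores <- log2(sweep(num / den, 2L, background, "/"))
  structure(list(scores = scores, background = background,
                 pseudocount = pseudocount, n_eff = n_eff,
                 all_gap = n_eff == 0), class = "PSSMMatrix")
}

#' Conservation score of a candidate substitution
#'
#' Looks up the PSSM score (bits) of the target residue at the alignment
#' column mapped to a structure residue id. The design filter accepts
#' substitutions with score > -4.0 bits.
#'
#' @param pssm a [compute_pssm()] result.
#' @param res_id structure residue id.
#' @param to_aa 1-letter target residue.
#' @param offset integer added to `res_id` to obtain the alignment column
#'   (default 0: column i maps to residue i), or a named integer vector
#'   mapping residue ids to columns.
#' @return Score in bits.
#' @export
score_mutation <- function(pssm, res_id, to_aa, offset = 0L) {
  to_aa <- toupper(to_aa)
  if (!to_aa %in% AA1) stop("unknown amino-acid code: ", to_aa)
  col <- if (length(offset) > 1L || !is.null(names(offset))) {
    v <- offset[as.character(res_id)]
    if (is.na(v)) stop("mapping error: residue ", res_id, " not in offset map")
    as.integer(v)
  } else res_id + as.integer(offset)
  if (is.na(col) || col < 1L || col > nrow(pssm$scores))
    stop("mapping error: residue ", res_id, " maps outside the alignment")
  unname(pssm$scores[col, to_aa])
}

#' Write a PSSM as TSV (position, 20 per-residue scores)
#'
#' @param pssm a `PSSMMatrix`.
#' @param path output file.
#' @export
write_pssm <- function(pssm, path) {
  df <- data.frame(position = seq_len(nrow(pssm$scores)), pssm$scores,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
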