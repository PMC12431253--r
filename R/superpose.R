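# Least-squares rigid-body superposition (Kabsch) and derived analytics.

# Kabsch: rotation/translation minimizing ||R p + t - q||^2 over atom pairs.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)          # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, sv = sv$d)
}

#' Superpose one structure onto another
#'
#' Least-squares rigid-body fit (Kabsch, via SVD with reflection correction)
#' of the selected atoms of `mobile` onto the matching atoms of `reference`.
#'
#' @param mobile,reference `Structure` objects sharing the selected atoms.
#' @param sel a [selection()]; defaults to all C-alpha atoms.
#' @return A `SuperpositionResult`: list with `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom) and `rmsd` (Angstrom, the least-squares
#'   minimum over rigid transforms of the selected atoms).
#' @export
superpose <- function(mobile, reference, sel = selection_ca()) {
  im <- select_atoms(mobile, sel)
  ir <- select_atoms(reference, sel)
  if (length(im) != length(ir))
    stop("selection yields different atom counts in mobile and reference")
  if (length(im) < 3L)
    stop("degenerate selection: need at least 3 atom pairs")
  P <- mobile$xyz[im, , drop = FALSE]
  Q <- reference$xyz[ir, , drop = FALSE]
  # collinearity check: centered reference must span at least a plane
  svQ <- svd(sweep(Q, 2L, colMeans(Q)))$d
  if (svQ[2L] < 1e-8 * max(svQ[1L], 1))
    stop("degenerate selection: selected atoms are collinear")
  fit <- kabsch_fit(P, Q)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd), class = "SuperpositionResult")
}

#' Apply a superposition to a whole structure
#'
#' @param x a `Structure`.
#' @param fit a `SuperpositionResult` from [superpose()].
#' @return The transformed `Structure`.
#' @export
transform_structure <- function(x, fit) {
  xyz <- x$xyz %*% t(fit$rotation)
  xyz <- sweep(xyz, 2L, fit$translation, "+")
  new_structure(x$atoms, xyz, label = x$label)
}

#' Pairwise RMSD matrix over a set of structures
#'
#' Each entry (i, j) is the least-squares RMSD of structure i fitted onto
#' structure j over the selected atoms; the matrix is symmetric with a zero
#' diagonal.
#'
#' @param structures list of `Structure` objects (or an `Ensemble`).
#' @param sel a [selection()], e.g. [selection_ca()] or [selection_backbone()].
#' @return Symmetric numeric matrix (Angstrom), labelled by structure labels.
#' @export
pairwise_rmsd_matrix <- function(structures, sel = selection_ca()) {
  if (inherits(structures, "Ensemble")) structures <- structures$members
  n <- length(structures)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) m[i, j] <- superpose(structures[[i]], structures[[j]], sel)$rmsd
  }
  m <- m + t(m)
  labs <- vapply(structures, function(s) s$label, character(1L))
  if (any(nzchar(labs))) dimnames(m) <- list(labs, labs)
  m
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of the selected atom of each residue about its mean position across
#' ensemble members: `sqrt(mean_k ||x_k - mean(x)||^2)`. With `fit = TRUE`
#' every member is first superposed onto member 1 over `fit_sel` (default:
#' the same selection).
#'
#' @param ensemble an `Ensemble` with at least 2 members.
#' @param sel atoms measured (default one C-alpha per residue).
#' @param fit logical; superpose members onto member 1 first.
#' @param fit_sel selection used for the fit (defaults to `sel`).
#' @return A data.frame of class `FlexibilityProfile` with columns `chain`,
#'   `res_id`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ensemble, sel = selection_ca(), fit = TRUE,
                         fit_sel = sel) {
  if (length(ensemble$members) < 2L)
    stop("insufficient frames: RMSF needs at least 2 ensemble members")
  members <- ensemble$members
  if (fit) {
    ref <- members[[1L]]
    members <- lapply(members, function(s)
      transform_structure(s, superpose(s, ref, fit_sel)))
  }
  idx <- select_atoms(members[[1L]], sel)
  nf <- length(members)
  coords <- array(0, dim = c(length(idx), 3L, nf))
  for (k in seq_len(nf)) coords[, , k] <- members[[k]]$xyz[idx, , drop = FALSE]
  mean_pos <- apply(coords, c(1L, 2L), mean)
  sq <- matrix(0, length(idx), nf)
  for (k in seq_len(nf)) sq[, k] <- rowSums((coords[, , k] - mean_pos)^2)
  out <- data.frame(
    chain = members[[1L]]$atoms$chain[idx],
    res_id = members[[1L]]$atoms$res_id[idx],
    rmsf = sqrt(rowMeans(sq)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("FlexibilityProfile", class(out))
  out
}
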