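# Structure comparison: C-alpha extraction from PDB/mmCIF files, Kabsch
# least-squares superposition, and sequence-aligned iterative
# superposition with outlier rejection.

#' Extract C-alpha coordinates of one protein chain
#'
#' Reads a PDB or mmCIF file (dispatch on file extension), takes the
#' first model, the first alternate location, and either the named chain
#' or the chain with the most C-alpha atoms.  Residues lacking a C-alpha
#' are skipped.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param chain Optional chain identifier.
#' @param structure_id Identifier; defaults to the file name.
#' @return Object of class `chain_coords`: `structure_id`,
#'   `residue_numbers`, `one_letter_sequence`, `calpha_xyz` (n x 3 matrix,
#'   Angstroms).
#' @export
read_calpha <- function(path, chain = NULL, structure_id = NULL) {
  if (!file.exists(path) || file.size(path) == 0)
    stop_bad("cannot read structure file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
    else bio3d::read.pdb(path, multi = FALSE),
    error = function(e) stop_bad("failed to parse '", path, "': ",
                                 conditionMessage(e)))
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  alt_ok <- is.na(ca$alt) | ca$alt %in% c("", "A")
  ca <- ca[alt_ok, , drop = FALSE]
  if (!nrow(ca)) stop_bad("no protein C-alpha atoms in '", path, "'")
  if (is.null(chain)) {
    chain <- names(sort(table(ca$chain), decreasing = TRUE))[1]
  } else if (!chain %in% ca$chain) {
    stop_bad("chain '", chain, "' not found in '", path, "'")
  }
  ca <- ca[ca$chain == chain, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]   # first altloc / copy
  aa1 <- suppressWarnings(bio3d::aa321(ca$resid))
  aa1[is.na(aa1)] <- "X"
  structure(list(
    structure_id = structure_id %||% sub("\\.[^.]*$", "", basename(path)),
    chain = chain,
    residue_numbers = ca$resno,
    one_letter_sequence = paste(aa1, collapse = ""),
    calpha_xyz = unname(cbind(ca$x, ca$y, ca$z))),
    class = "chain_coords")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a chain_coords object from raw parts
#'
#' Convenience constructor (used e.g. for synthetic chains).
#'
#' @param structure_id Identifier.
#' @param sequence One-letter sequence (string).
#' @param xyz n x 3 coordinate matrix (Angstroms).
#' @param residue_numbers Optional residue numbering (default 1..n).
#' @return A `chain_coords` object.
#' @export
chain_coords <- function(structure_id, sequence, xyz,
                         residue_numbers = seq_len(nrow(xyz))) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3,
            nchar(sequence) == nrow(xyz),
            length(residue_numbers) == nrow(xyz),
            all(is.finite(xyz)))
  structure(list(structure_id = structure_id, chain = "A",
                 residue_numbers = residue_numbers,
                 one_letter_sequence = toupper(sequence),
                 calpha_xyz = unname(xyz)),
            class = "chain_coords")
}

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation (SVD with reflection correction, so
#' det(R) = +1) and translation minimising the RMSD between paired
#' coordinates, mapping `pairs_a` onto `pairs_b`:
#' `fitted = pairs_a %*% t(rotation) + translation`.
#'
#' @param pairs_a,pairs_b Equal-length n x 3 coordinate matrices
#'   (n >= 3, not all collinear).
#' @return Object of class `superposition`: `rotation` (3 x 3 proper
#'   orthonormal), `translation` (length-3), `rmsd` (Angstroms),
#'   `n_pairs`, `iterations`.
#' @export
kabsch <- function(pairs_a, pairs_b) {
  pairs_a <- as.matrix(pairs_a); pairs_b <- as.matrix(pairs_b)
  if (nrow(pairs_a) != nrow(pairs_b) || ncol(pairs_a) != 3 ||
      ncol(pairs_b) != 3)
    stop_bad("coordinate sets must be equal-length n x 3 matrices")
  n <- nrow(pairs_a)
  if (n < 3) stop_bad("need >= 3 coordinate pairs")
  if (!all(is.finite(pairs_a)) || !all(is.finite(pairs_b)))
    stop_bad("coordinates must be finite")
  ca <- colMeans(pairs_a); cb <- colMeans(pairs_b)
  A <- sweep(pairs_a, 2, ca); B <- sweep(pairs_b, 2, cb)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cb - R %*% ca)
  fitted <- pairs_a %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - pairs_b)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_pairs = n, iterations = 1L),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", format(round(x$rmsd, 4)), " A over ",
      x$n_pairs, " pairs (", x$iterations, " iteration",
      if (x$iterations != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Sequence-aligned C-alpha superposition of two chains
#'
#' Pairs C-alpha atoms via global sequence alignment of the two
#' one-letter sequences (columns with gaps or non-standard residues are
#' excluded), runs [kabsch()], then iteratively discards pairs whose
#' post-fit distance exceeds `reject_multiplier` times the current RMSD
#' and refits, until no pair is discarded or `max_iterations` is
#' reached.  The RMSD is non-increasing across rejection iterations.
#'
#' @param a,b `chain_coords` objects (>= 50 residues each).
#' @param reject_multiplier Outlier cutoff as a multiple of the current
#'   RMSD (default 2).
#' @param max_iterations Maximum refinement iterations (default 5).
#' @param params [align_params()] for the sequence alignment.
#' @return A `superposition` object with final `rmsd`, `n_pairs`,
#'   `iterations`, plus `pairs_a_idx`/`pairs_b_idx` (indices of the
#'   C-alpha pairs used).
#' @export
superpose_structures <- function(a, b, reject_multiplier = 2,
                                 max_iterations = 5,
                                 params = align_params()) {
  stopifnot(inherits(a, "chain_coords"), inherits(b, "chain_coords"))
  if (nchar(a$one_letter_sequence) < 50 || nchar(b$one_letter_sequence) < 50)
    stop_bad("both chains must have >= 50 residues")
  aln <- global_align(a$one_letter_sequence, b$one_letter_sequence,
                      a_id = a$structure_id, b_id = b$structure_id,
                      params = params)
  ra <- seq_chars(aln$aligned_ref)
  rb <- seq_chars(aln$aligned_query)
  ia <- cumsum(ra != "-")
  ib <- cumsum(rb != "-")
  keep <- ra %in% AA20 & rb %in% AA20
  idx_a <- ia[keep]; idx_b <- ib[keep]
  if (length(idx_a) < 3) stop_bad("fewer than 3 alignable residue pairs")

  A <- a$calpha_xyz[idx_a, , drop = FALSE]
  B <- b$calpha_xyz[idx_b, , drop = FALSE]
  sel <- seq_len(nrow(A))
  fit <- kabsch(A, B)
  iter <- 1L
  while (iter < max_iterations && fit$rmsd > 1e-8) {
    fitted <- A[sel, , drop = FALSE] %*% t(fit$rotation) +
      matrix(fit$translation, length(sel), 3, byrow = TRUE)
    d <- sqrt(rowSums((fitted - B[sel, , drop = FALSE])^2))
    keep2 <- d <= reject_multiplier * fit$rmsd
    if (all(keep2)) break
    sel <- sel[keep2]
    if (length(sel) < 3) stop_bad("fewer than 3 surviving pairs")
    fit <- kabsch(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
    iter <- iter + 1L
  }
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_pairs = length(sel),
                 iterations = iter,
                 pairs_a_idx = idx_a[sel], pairs_b_idx = idx_b[sel]),
            class = "superposition")
}
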