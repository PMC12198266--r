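# Global pairwise alignment, reference-position anchoring, and a minimal
# progressive multiple aligner used by the logo and phylogeny stages.

#' Alignment parameters
#'
#' @param submat 20x20 substitution matrix (default BLOSUM62).
#' @param gap_open Gap opening penalty (positive; a gap of length k costs
#'   `gap_open + k * gap_ext`).
#' @param gap_ext Gap extension penalty (positive, per gapped column).
#' @return A list of parameters for the alignment functions.
#' @export
align_params <- function(submat = blosum62(), gap_open = 10, gap_ext = 0.5) {
  stopifnot(is.matrix(submat), nrow(submat) == 20, ncol(submat) == 20,
            gap_open >= 0, gap_ext >= 0)
  m <- submat[AA20, AA20]
  list(submat = m, gap_open = gap_open, gap_ext = gap_ext)
}

#' Optimal global pairwise alignment (Needleman-Wunsch / Gotoh)
#'
#' Three-state affine-gap dynamic programming with deterministic
#' tie-breaking (prefer diagonal, then up, then left during traceback).
#'
#' @param a,b Protein sequences (single strings), `a` is treated as the
#'   reference row.
#' @param a_id,b_id Identifiers recorded in the alignment.
#' @param params [align_params()] list.
#' @return Object of class `alignment`: `ref_id`, `query_id`,
#'   `aligned_ref`, `aligned_query` (equal-length gapped strings) and
#'   `score`.
#' @export
global_align <- function(a, b, a_id = "ref", b_id = "query",
                         params = align_params()) {
  if (!is.character(a) || !nzchar(a) || !is.character(b) || !nzchar(b))
    stop_bad("both sequences must be non-empty strings")
  a <- toupper(a); b <- toupper(b)
  ia <- matrix(seq_to_int(a), nrow = 1)
  ib <- matrix(seq_to_int(b), nrow = 1)
  res <- profile_align_cpp(ia, ib, params$submat,
                           params$gap_open, params$gap_ext)
  ca <- seq_chars(a); cb <- seq_chars(b)
  ar <- ifelse(res$path_a > 0, ca[pmax(res$path_a, 1L)], "-")
  aq <- ifelse(res$path_b > 0, cb[pmax(res$path_b, 1L)], "-")
  structure(list(ref_id = a_id, query_id = b_id,
                 aligned_ref = paste(ar, collapse = ""),
                 aligned_query = paste(aq, collapse = ""),
                 score = res$score),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> ", x$ref_id, " vs ", x$query_id,
      "  score ", format(x$score), "\n", sep = "")
  invisible(x)
}

#' Reference anchor: catalytic and typing positions on a reference enzyme
#'
#' Holds a reference AAO sequence together with the 1-based residue
#' numbers of its two catalytic histidines and its two active-site typing
#' positions.  Numbering is taken on the sequence exactly as supplied (no
#' signal-peptide arithmetic).  The classical anchors are PeAAO
#' (catalytic H502/H546, typing Y92/F501) for fungi, ShAAO (H456/H500,
#' F92/F455) for bacteria and CpAAO (typing Y128/Y535) for arthropods.
#'
#' @param reference_id Identifier of the reference sequence.
#' @param sequence Reference protein sequence (string).
#' @param catalytic_positions Two 1-based residue numbers (histidines in
#'   the reference).
#' @param typing_positions Two 1-based residue numbers (position a, then
#'   position b).
#' @return Object of class `reference_anchor`.
#' @export
reference_anchor <- function(reference_id, sequence,
                             catalytic_positions, typing_positions) {
  sequence <- toupper(sequence)
  pos <- c(catalytic_positions, typing_positions)
  if (length(catalytic_positions) != 2L || length(typing_positions) != 2L)
    stop_bad("need exactly two catalytic and two typing positions")
  if (anyDuplicated(pos))
    stop_bad("anchor positions must be distinct")
  if (any(pos < 1L) || any(pos > nchar(sequence)))
    stop_bad("anchor positions outside reference length")
  structure(list(reference_id = reference_id,
                 sequence = sequence,
                 catalytic_positions = as.integer(catalytic_positions),
                 typing_positions = as.integer(typing_positions)),
            class = "reference_anchor")
}

#' Map reference residue numbers to query positions through an alignment
#'
#' For each requested 1-based reference position, returns the 1-based
#' query position aligned to that reference column (NA when the query has
#' a gap there, i.e. the position is unmapped), plus the query residue.
#'
#' @param aln An [global_align()] alignment (reference in the first row).
#' @param positions Integer vector of 1-based reference residue numbers.
#' @return Data frame `ref_pos`, `query_pos` (NA = unmapped),
#'   `query_residue` (NA = unmapped).  Mapped positions are strictly
#'   increasing in `ref_pos` order.
#' @export
map_positions <- function(aln, positions) {
  stopifnot(inherits(aln, "alignment"))
  rc <- seq_chars(aln$aligned_ref)
  qc <- seq_chars(aln$aligned_query)
  ref_idx <- cumsum(rc != "-")
  qry_idx <- cumsum(qc != "-")
  ref_len <- ref_idx[length(ref_idx)]
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > ref_len))
    stop_bad("anchor position outside reference length (", ref_len, ")")
  cols <- match(positions, ifelse(rc != "-", ref_idx, NA_integer_))
  qpos <- ifelse(qc[cols] != "-", qry_idx[cols], NA_integer_)
  qres <- ifelse(qc[cols] != "-", qc[cols], NA_character_)
  data.frame(ref_pos = positions, query_pos = as.integer(qpos),
             query_residue = qres, stringsAsFactors = FALSE)
}

#' Anchor a query sequence against a reference
#'
#' Convenience wrapper: globally aligns the query to the anchor's
#' reference sequence and maps the catalytic and typing positions.
#'
#' @param query Query sequence (string).
#' @param query_id Query identifier.
#' @param anchor A [reference_anchor()].
#' @param params [align_params()].
#' @return List with the `alignment`, the full position `map` (data
#'   frame), and convenience entries `catalytic` and `typing` (rows of the
#'   map), plus the alignment `score`.
#' @export
anchor_query <- function(query, query_id, anchor, params = align_params()) {
  stopifnot(inherits(anchor, "reference_anchor"))
  aln <- global_align(anchor$sequence, query,
                      a_id = anchor$reference_id, b_id = query_id,
                      params = params)
  pos <- c(anchor$catalytic_positions, anchor$typing_positions)
  m <- map_positions(aln, pos)
  list(alignment = aln, map = m,
       catalytic = m[1:2, , drop = FALSE],
       typing = m[3:4, , drop = FALSE],
       score = aln$score)
}

# route a record to a kingdom: explicit hint wins, otherwise the anchor
# with the highest global alignment score
route_kingdom <- function(seq, anchors, hint = NULL, params = align_params()) {
  if (!is.null(hint) && !is.na(hint)) {
    if (!hint %in% names(anchors))
      stop_bad("unknown kingdom '", hint, "'")
    return(hint)
  }
  scores <- vapply(anchors, function(an)
    global_align(an$sequence, seq, params = params)$score, numeric(1))
  names(anchors)[which.max(scores)]
}

# ---------------------------------------------------------------------------
# progressive multiple alignment

# fractional common 3-mer distance between two sequences
kmer_distance <- function(a, b, k = 3L) {
  ka <- substring(a, seq_len(max(nchar(a) - k + 1L, 0L)),
                  seq_len(max(nchar(a) - k + 1L, 0L)) + k - 1L)
  kb <- substring(b, seq_len(max(nchar(b) - k + 1L, 0L)),
                  seq_len(max(nchar(b) - k + 1L, 0L)) + k - 1L)
  ta <- table(ka); tb <- table(kb)
  shared <- sum(pmin(ta[intersect(names(ta), names(tb))],
                     tb[intersect(names(ta), names(tb))]))
  denom <- max(min(length(ka), length(kb)), 1L)
  1 - shared / denom
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from pairwise 3-mer distances by neighbor joining,
#' then performs profile-profile global alignment (affine gaps) up the
#' guide tree.  Rows all have equal length and degapping any row recovers
#' the corresponding input sequence exactly.  For two sequences this
#' reduces to [global_align()].
#'
#' This is a deliberately small progressive aligner for desk-scale
#' analyses; an externally computed alignment (aligned FASTA) can be used
#' anywhere the package consumes an MSA.
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @param params [align_params()].
#' @return Named character vector of equal-length gapped rows, in input
#'   order.
#' @export
progressive_msa <- function(seqs, params = align_params()) {
  if (length(seqs) < 2L) stop_bad("progressive_msa needs >= 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_bad("sequences must have unique names")
  seqs <- toupper(seqs)
  n <- length(seqs)

  prof <- lapply(seqs, function(s) matrix(seq_to_int(s), nrow = 1))
  rows_of <- lapply(seq_len(n), identity)

  merge_pair <- function(pa, pb) {
    res <- profile_align_cpp(pa, pb, params$submat,
                             params$gap_open, params$gap_ext)
    L <- length(res$path_a)
    out <- matrix(20L, nrow = nrow(pa) + nrow(pb), ncol = L)
    ka <- res$path_a > 0
    out[seq_len(nrow(pa)), ka] <- pa[, res$path_a[ka], drop = FALSE]
    kb <- res$path_b > 0
    out[nrow(pa) + seq_len(nrow(pb)), kb] <- pb[, res$path_b[kb], drop = FALSE]
    out
  }

  if (n == 2L) {
    merged <- merge_pair(prof[[1]], prof[[2]])
    order_idx <- c(1L, 2L)
  } else {
    D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]])
    }
    guide <- neighbor_joining(D)
    guide <- stats::reorder(guide, "postorder")
    ntip <- length(guide$tip.label)
    node_prof <- vector("list", ntip + guide$Nnode)
    node_rows <- vector("list", ntip + guide$Nnode)
    tip_idx <- match(guide$tip.label, names(seqs))
    for (t in seq_len(ntip)) {
      node_prof[[t]] <- prof[[tip_idx[t]]]
      node_rows[[t]] <- tip_idx[t]
    }
    parents <- unique(guide$edge[, 1])
    for (p in parents) {                      # postorder: children ready
      ch <- guide$edge[guide$edge[, 1] == p, 2]
      acc <- node_prof[[ch[1]]]
      rows <- node_rows[[ch[1]]]
      for (c2 in ch[-1]) {
        acc <- merge_pair(acc, node_prof[[c2]])
        rows <- c(rows, node_rows[[c2]])
      }
      node_prof[[p]] <- acc
      node_rows[[p]] <- rows
    }
    root <- parents[length(parents)]
    merged <- node_prof[[root]]
    order_idx <- node_rows[[root]]
  }

  out <- character(n)
  for (r in seq_len(nrow(merged)))
    out[order_idx[r]] <- int_to_seq(merged[r, ])
  names(out) <- names(seqs)
  out
}
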