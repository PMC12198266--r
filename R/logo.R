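# Sequence-logo statistics: per-column information content in bits with
# the optional small-sample correction, and letter heights proportional
# to residue frequencies (the numeric content behind WebLogo-style motif
# logos).

#' Information content of one alignment column
#'
#' R = log2(20) - (H_obs + e(n)), where H_obs is the Shannon entropy of
#' the observed residue frequencies and e(n) = (s - 1) / (2 ln(2) n) with
#' s = 20 is the small-sample correction; the result is clamped at zero
#' from below.
#'
#' @param counts Named non-negative integer vector of residue counts
#'   (n = sum(counts) must be >= 1).
#' @param small_sample_correction Apply e(n)?  Default off.
#' @return Information content in bits, in [0, log2(20)].
#' @examples
#' column_information(c(H = 20))            # log2(20) = 4.3219
#' column_information(c(A = 3, C = 1), TRUE) # 0.0842
#' @export
column_information <- function(counts, small_sample_correction = FALSE) {
  if (any(counts < 0)) stop_bad("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop_bad("column has no observations")
  f <- counts[counts > 0] / n
  h <- -sum(f * log2(f))
  e <- if (small_sample_correction) (20 - 1) / (2 * log(2) * n) else 0
  max(0, log2(20) - h - e)
}

#' Per-column logo statistics over reference-numbered columns of an MSA
#'
#' Translates 1-based reference residue numbers into alignment columns
#' via the reference row, counts residues per column with gaps excluded,
#' and computes information content and letter heights (frequency times
#' information).  A reference position falling on a column where every
#' other row is gapped is emitted with `n_effective` 0 and a warning.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param reference_id Name of the reference row used for column
#'   numbering.
#' @param positions 1-based residue numbers on the (degapped) reference.
#' @param small_sample_correction `"auto"` (on when n_effective < 50),
#'   `TRUE` or `FALSE`.
#' @param include_reference Count the reference row itself?  Default
#'   FALSE so logos describe the candidate set, not the anchor.
#' @return Data frame with `column_index` (reference numbering),
#'   `n_effective`, `information_bits`, and one `height_<residue>` column
#'   per canonical residue.
#' @export
build_logo <- function(msa, reference_id, positions,
                       small_sample_correction = "auto",
                       include_reference = FALSE) {
  if (!reference_id %in% names(msa))
    stop_bad("reference row '", reference_id, "' not in alignment")
  if (length(unique(nchar(msa))) != 1L)
    stop_bad("alignment rows must have equal length")
  ref <- seq_chars(msa[[reference_id]])
  ref_idx <- cumsum(ref != "-")
  cols <- match(as.integer(positions), ifelse(ref != "-", ref_idx, NA))
  if (anyNA(cols))
    stop_bad("reference positions outside reference length")
  rows <- if (include_reference) msa else msa[names(msa) != reference_id]
  M <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))

  out <- lapply(seq_along(positions), function(k) {
    col <- M[, cols[k]]
    col <- col[col %in% AA20]
    n_eff <- length(col)
    heights <- setNames(numeric(20), AA20)
    if (n_eff == 0L) {
      warning("reference position ", positions[k],
              " falls on an all-gap column")
      bits <- 0
    } else {
      counts <- table(factor(col, levels = AA20))
      corr <- if (identical(small_sample_correction, "auto")) n_eff < 50
              else isTRUE(small_sample_correction)
      bits <- column_information(as.integer(counts), corr)
      heights[] <- as.integer(counts) / n_eff * bits
    }
    cbind(data.frame(column_index = positions[k], n_effective = n_eff,
                     information_bits = bits),
          as.data.frame(as.list(setNames(heights,
                                         paste0("height_", AA20)))))
  })
  do.call(rbind, out)
}

#' Write logo statistics as TSV
#' @param logo Data frame from [build_logo()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_logo_tsv <- function(logo, path) {
  utils::write.table(logo, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
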