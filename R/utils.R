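# Shared constants and small helpers.

# canonical 20-letter amino-acid alphabet (alphabetical one-letter codes)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue classes used by the typing rules; G is deliberately excluded from
# ALIPHATIC because it anchors fungal type III on its own
AA_CLASSES <- list(
  AROMATIC       = c("F", "W", "Y"),
  GLY            = "G",
  ALA_GLY        = c("A", "G"),
  ALIPHATIC      = c("A", "V", "L", "I", "M"),
  UNCHARGED_POLAR = c("S", "T", "N", "Q", "C"),
  POSITIVE       = c("K", "R", "H")
)

KINGDOMS <- c("fungi", "bacteria", "arthropod")

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 canonical residues
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, restricted to the
#' 20 canonical amino acids, in the fixed alphabet order used throughout
#' the package.
#'
#' @return A 20x20 numeric matrix with residue one-letter row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$blosum62
}

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# map residue letters to 0-based alphabet indices; gaps / non-standard -> 20
seq_to_int <- function(x) {
  ch <- if (length(x) == 1L && nchar(x) > 1L) seq_chars(x) else x
  idx <- match(ch, AA20)
  idx[is.na(idx)] <- 21L
  as.integer(idx - 1L)
}

int_to_seq <- function(v) {
  ch <- c(AA20, "-")[pmin(v + 1L, 21L)]
  paste(ch, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write protein sequences to a FASTA file (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(gsub("-", "", seqs, fixed = TRUE))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

# Write an *aligned* FASTA (keeps gap characters)
write_aligned_fasta <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rows)) {
    writeLines(paste0(">", names(rows)[i]), con)
    s <- rows[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

stop_bad <- function(...) stop(..., call. = FALSE)
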