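# PROSITE-style signature parsing and scanning.
#
# Grammar (elements separated by '-'):
#   A          literal residue
#   x          any residue
#   [ACD]      alternatives
#   {ACD}      exclusion set (matches any residue NOT listed, and never 'X')
#   elem(n)    fixed repeat, elem(n,m) range repeat
#   <          N-terminal anchor (prefix of first element)
#   >          C-terminal anchor (suffix of last element)
# A trailing '.' (as in the PROSITE database dumps) is tolerated.
#
# Matching semantics: case-insensitive sequences canonicalised to
# uppercase; a sequence 'X' matches only the ANY element; for range
# repeats the scan reports, at each matching start, the leftmost-shortest
# match (non-greedy).  Overlapping matches at distinct starts are all
# reported.

ELEMENT_RX <- "^(<?)(\\[([A-Z]+)\\]|\\{([A-Z]+)\\}|[A-Z]|x)(\\((\\d+)(,(\\d+))?\\))?(>?)$"

#' Parse a PROSITE-style signature into an executable pattern
#'
#' Parses signature text such as the GMC-family PS00623 signature
#' `[GA]-[RKNC]-x-[LIVW]-G(2)-[GST](2)-x-[LIVM]-[NH]-x(3)-[FYWA]-x(2)-[PAG]-x(5)-[DNESHQA]`
#' into an ordered list of pattern elements.  Parsing is lossless: the
#' original text is preserved in the returned object.
#'
#' @param text Signature string in PROSITE grammar (see Details).
#' @param id Pattern identifier (e.g. `"PS00623"`).
#' @return An object of class `prosite_pattern` with fields `pattern_id`,
#'   `elements`, `source_text`, `min_span`, `max_span`.
#' @examples
#' p <- parse_prosite("G-x-G-x(2)-G-x(18)-E", id = "ADP")
#' p$min_span  # 25
#' @export
parse_prosite <- function(text, id = "pattern") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop_bad("signature text must be a single non-empty string")
  src <- text
  text <- sub("\\.$", "", trimws(text))
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L || any(!nzchar(toks)))
    stop_bad("empty element in signature '", src, "'")
  elements <- vector("list", length(toks))
  for (k in seq_along(toks)) {
    m <- regexec(ELEMENT_RX, toks[k])[[1]]
    if (m[1] == -1L)
      stop_bad("syntax error in element ", k, " ('", toks[k],
               "') of signature '", src, "' (check brackets and repeats)")
    parts <- regmatches(toks[k], regexec(ELEMENT_RX, toks[k]))[[1]]
    core <- parts[3]
    anchor_start <- nzchar(parts[2])
    anchor_end <- nzchar(parts[10])
    if (anchor_start && k != 1L)
      stop_bad("element ", k, ": '<' anchor only allowed on the first element")
    if (anchor_end && k != length(toks))
      stop_bad("element ", k, ": '>' anchor only allowed on the last element")
    if (core == "x") {
      type <- "any"; residues <- character(0)
    } else if (startsWith(core, "[")) {
      type <- "set"; residues <- seq_chars(parts[4])
    } else if (startsWith(core, "{")) {
      type <- "not"; residues <- seq_chars(parts[5])
    } else {
      type <- "set"; residues <- core
    }
    if (length(residues) && !all(residues %in% AA20))
      stop_bad("element ", k, ": non-residue letter in '", toks[k], "'")
    if (type == "not" && length(setdiff(AA20, residues)) == 0L)
      stop_bad("element ", k, ": exclusion set leaves no allowed residue")
    min_rep <- max_rep <- 1L
    if (nzchar(parts[6])) {
      min_rep <- as.integer(parts[7])
      max_rep <- if (nzchar(parts[8])) as.integer(parts[9]) else min_rep
      if (is.na(min_rep) || min_rep < 1L)
        stop_bad("element ", k, ": repeat count must be >= 1")
      if (is.na(max_rep) || max_rep < min_rep)
        stop_bad("element ", k, ": invalid repeat range")
    }
    elements[[k]] <- list(type = type, residues = residues,
                          min_rep = min_rep, max_rep = max_rep,
                          anchor_start = anchor_start, anchor_end = anchor_end)
  }
  structure(
    list(pattern_id = id,
         elements = elements,
         source_text = src,
         min_span = sum(vapply(elements, `[[`, 1L, "min_rep")),
         max_span = sum(vapply(elements, `[[`, 1L, "max_rep"))),
    class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern>", x$pattern_id, "\n  ", x$source_text,
      "\n  elements: ", length(x$elements),
      "  span: ", x$min_span,
      if (x$max_span > x$min_span) paste0("-", x$max_span) else "", "\n",
      sep = "")
  invisible(x)
}

# compile a pattern to a PCRE regex; range repeats are lazy so that the
# capture inside a lookahead yields the leftmost-shortest match per start
prosite_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(e) {
    base <- switch(e$type,
      any = ".",
      set = if (length(e$residues) == 1L) e$residues
            else paste0("[", paste(e$residues, collapse = ""), "]"),
      not = paste0("[^", paste(e$residues, collapse = ""), "X]"))
    rep <- if (e$min_rep == e$max_rep) {
      if (e$min_rep == 1L) "" else paste0("{", e$min_rep, "}")
    } else {
      paste0("{", e$min_rep, ",", e$max_rep, "}?")
    }
    paste0(if (e$anchor_start) "^" else "", base, rep,
           if (e$anchor_end) "$" else "")
  }, character(1))
  paste(parts, collapse = "")
}

#' Scan a protein sequence for PROSITE signature matches
#'
#' Reports every match whose 0-based start lies in `window` (the whole
#' sequence if absent), in ascending start order.  Overlapping matches at
#' distinct starts are all reported; at a single start, range-repeat
#' patterns yield the leftmost-shortest match.  A sequence residue `X`
#' matches only the ANY (`x`) element.
#'
#' @param pattern A [parse_prosite()] pattern.
#' @param seq A single protein sequence (string; canonicalised to upper
#'   case).
#' @param seq_id Identifier recorded in the hits.
#' @param window Optional 0-based half-open `c(start, end)` interval that
#'   the match *start* must fall in.
#' @return A data frame with columns `pattern_id`, `seq_id`, `start`,
#'   `end` (0-based half-open) and `matched_text`; zero rows when there is
#'   no match.
#' @export
scan_motif <- function(pattern, seq, seq_id = "seq", window = NULL) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  if (!is.character(seq) || length(seq) != 1L)
    stop_bad("seq must be a single string")
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(pattern_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rx <- paste0("(?=(", prosite_regex(pattern), "))")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)                       # 1-based
  lens <- attr(m, "capture.length")[, 1L]
  keep <- lens > 0L
  starts <- starts[keep]; lens <- lens[keep]
  if (!length(starts)) return(empty)
  start0 <- starts - 1L
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] < 0 || window[2] < window[1])
      stop_bad("window must be a valid 0-based half-open interval")
    keep <- start0 >= window[1] & start0 < window[2]
    starts <- starts[keep]; lens <- lens[keep]; start0 <- start0[keep]
  }
  if (!length(starts)) return(empty)
  data.frame(pattern_id = pattern$pattern_id,
             seq_id = seq_id,
             start = start0,
             end = start0 + lens,
             matched_text = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

# does a single character satisfy a pattern element?
element_matches <- function(e, ch) {
  switch(e$type,
    any = TRUE,
    set = ch %in% e$residues,
    not = ch != "X" && !(ch %in% e$residues))
}

#' Exhaustive reference scanner (test oracle for [scan_motif()])
#'
#' Enumerates every start position and every repeat-width assignment by
#' depth-first search, trying smaller widths first, which reproduces the
#' non-greedy (leftmost-shortest) semantics of [scan_motif()] without any
#' regular-expression machinery.  Intended for cross-checking; quadratic
#' and slow on long sequences.
#'
#' @inheritParams scan_motif
#' @return Same shape as [scan_motif()].
#' @export
brute_force_scan <- function(pattern, seq, seq_id = "seq", window = NULL) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  els <- pattern$elements
  ne <- length(els)

  match_from <- function(pos, k) {      # pos: next 0-based index to consume
    if (k > ne) return(pos)
    e <- els[[k]]
    if (e$anchor_start && pos != 0L) return(-1L)
    for (w in e$min_rep:e$max_rep) {
      if (pos + w > n) break
      ok <- TRUE
      for (t in seq_len(w)) {
        if (!element_matches(e, ch[pos + t])) { ok <- FALSE; break }
      }
      if (!ok) next
      if (e$anchor_end && k == ne && pos + w != n) next
      r <- match_from(pos + w, k + 1L)
      if (r >= 0L) return(r)
    }
    -1L
  }

  rows <- list()
  starts <- 0:(max(n - 1L, 0L))
  if (!is.null(window))
    starts <- starts[starts >= window[1] & starts < window[2]]
  for (s in starts) {
    if (s + pattern$min_span > n) next
    r <- match_from(s, 1L)
    if (r >= 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        pattern_id = pattern$pattern_id, seq_id = seq_id,
        start = s, end = r,
        matched_text = substr(seq, s + 1L, r),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pattern_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Built-in GMC / AAO signatures
#'
#' The three conserved features screened for in putative AAO candidates:
#' the ADP-binding fingerprint of the Rossmann beta-alpha-beta element
#' (`G-x-G-x(2)-G-x(18)-E`), and the two GMC-superfamily PROSITE
#' signatures PS00623 (N-terminal region) and PS00624 (central portion).
#'
#' @return Named list of `prosite_pattern` objects: `adp`, `ps00623`,
#'   `ps00624`.
#' @export
aao_signatures <- function() {
  if (is.null(.pkg_cache$signatures)) {
    .pkg_cache$signatures <- list(
      adp = parse_prosite("G-x-G-x(2)-G-x(18)-E", id = "ADP_BINDING"),
      ps00623 = parse_prosite(
        paste0("[GA]-[RKNC]-x-[LIVW]-G(2)-[GST](2)-x-[LIVM]-[NH]-x(3)-",
               "[FYWA]-x(2)-[PAG]-x(5)-[DNESHQA]"),
        id = "PS00623"),
      ps00624 = parse_prosite(
        "[GS]-[PSTA]-x(2)-[ST]-[PS]-x-[LIVM](2)-x(2)-S-G-[LIVM]-G",
        id = "PS00624"))
  }
  .pkg_cache$signatures
}

#' Load signatures from a plain-text file
#'
#' One `id<TAB>pattern` per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the signature file.
#' @return Named list of `prosite_pattern` objects.
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop_bad("malformed signature line (need id<TAB>pattern): '", ln, "'")
    out[[f[1]]] <- parse_prosite(f[2], id = f[1])
  }
  out
}

#' Write motif hits as TSV
#'
#' Coordinates are 0-based half-open, stated in a header comment.
#'
#' @param hits Data frame from [scan_motif()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# motif hits; coordinates 0-based half-open", con)
  writeLines(paste(colnames(hits), collapse = "\t"), con)
  if (nrow(hits))
    utils::write.table(hits, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
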