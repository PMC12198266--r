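# Candidate selection: homology-hit threshold filtering plus retention of
# sequences displaying all conserved AAO features (ADP-binding motif,
# PS00623, PS00624, and the two catalytic histidines at the
# reference-equivalent positions).

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bit_score")

#' Region windows for the conserved-feature checks
#'
#' The signatures are positionally constrained: the ADP motif and PS00623
#' sit in the N-terminal region, PS00624 in the central portion.  The
#' defaults are deliberately permissive fractions of the sequence length:
#' N-terminal window = first 40 percent, central window = 30 to 75
#' percent.
#'
#' @param nterm_frac Fraction of the sequence forming the N-terminal
#'   window.
#' @param central_frac Length-2 fractions bounding the central window.
#' @return List with `nterm_frac`, `central_frac`.
#' @export
region_windows <- function(nterm_frac = 0.4, central_frac = c(0.3, 0.75)) {
  stopifnot(nterm_frac > 0, nterm_frac <= 1,
            length(central_frac) == 2L,
            central_frac[1] >= 0, central_frac[2] <= 1,
            central_frac[1] < central_frac[2])
  list(nterm_frac = nterm_frac, central_frac = central_frac)
}

window_for <- function(len, windows) {
  list(nterm = c(0, floor(windows$nterm_frac * len)),
       central = c(floor(windows$central_frac[1] * len),
                   floor(windows$central_frac[2] * len)))
}

#' Read a 12-column tabular homology hit table
#'
#' Header-less, tab-separated, `#` comment lines ignored (the standard
#' 12-column tabular output dialect of sequence homology search tools).
#'
#' @param path Path to the hit table.
#' @return Data frame with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), HIT_COLUMNS))
    return(validate_hit_table(df))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop_bad("unparseable hit-table row at line ", lineno[bad[1]],
             " (expected 12 tab-separated fields)")
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  colnames(df) <- HIT_COLUMNS
  num <- c("percent_identity", "alignment_length", "mismatches",
           "gap_opens", "q_start", "q_end", "s_start", "s_end",
           "evalue", "bit_score")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_bad("unparseable value in column '", cn, "' at line ",
               lineno[bad])
    }
    df[[cn]] <- v
  }
  validate_hit_table(df)
}

validate_hit_table <- function(df) {
  if (nrow(df)) {
    if (any(df$percent_identity < 0 | df$percent_identity > 100))
      stop_bad("percent_identity must lie in [0, 100]")
    if (any(df$evalue < 0)) stop_bad("e-values must be >= 0")
  }
  df
}

#' Write a hit table (12-column tabular)
#' @param hits Data frame with the 12 standard columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Threshold filtering of homology hits
#'
#' Retains subjects with percent identity strictly greater than
#' `min_identity` and e-value strictly smaller than `max_evalue` (read
#' literally from the selection thresholds "> 35 percent" and "< 1e-10").
#' A subject with several hits passes if any single hit passes.
#'
#' @param table Hit table data frame (see [read_hit_table()]).
#' @param min_identity Identity threshold (percent, strict `>`).
#' @param max_evalue E-value threshold (strict `<`).
#' @return Sorted character vector of passing subject ids.
#' @export
filter_hits <- function(table, min_identity = 35.0, max_evalue = 1e-10) {
  stopifnot(min_identity > 0, max_evalue > 0)
  validate_hit_table(table)
  pass <- table$percent_identity > min_identity & table$evalue < max_evalue
  sort(unique(table$subject_id[pass]))
}

#' Conserved-feature check for one candidate sequence
#'
#' A putative AAO must display, simultaneously: the ADP-binding motif
#' with its start in the N-terminal window; a PS00623 instance in the
#' N-terminal window; a PS00624 instance in the central window; and
#' histidine at both catalytic reference-equivalent positions (located by
#' global alignment to the kingdom's reference anchor).  Sequences
#' shorter than 100 residues are rejected with reason `"too_short"`
#' rather than raising an error.
#'
#' @param seq Candidate sequence (string).
#' @param seq_id Identifier.
#' @param anchor The kingdom's [reference_anchor()].
#' @param patterns Named list with `adp`, `ps00623`, `ps00624` patterns
#'   (default [aao_signatures()]).
#' @param windows [region_windows()].
#' @param params [align_params()].
#' @return One-row data frame (a FeatureReport): `seq_id`, the four
#'   feature booleans, `retained`, `reason`, and evidence columns
#'   (0-based motif starts, 1-based mapped catalytic positions).
#' @export
check_features <- function(seq, seq_id, anchor,
                           patterns = aao_signatures(),
                           windows = region_windows(),
                           params = align_params()) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len < 100L) {
    return(data.frame(seq_id = seq_id, has_adp = FALSE, has_ps00623 = FALSE,
                      has_ps00624 = FALSE, has_catalytic_his = FALSE,
                      retained = FALSE, reason = "too_short",
                      adp_start = NA_integer_, ps00623_start = NA_integer_,
                      ps00624_start = NA_integer_,
                      cat1_query_pos = NA_integer_,
                      cat2_query_pos = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  w <- window_for(len, windows)
  h_adp <- scan_motif(patterns$adp, seq, seq_id, window = w$nterm)
  h_623 <- scan_motif(patterns$ps00623, seq, seq_id, window = w$nterm)
  h_624 <- scan_motif(patterns$ps00624, seq, seq_id, window = w$central)
  anc <- anchor_query(seq, seq_id, anchor, params = params)
  cat_res <- anc$catalytic$query_residue
  has_his <- !anyNA(cat_res) && all(cat_res == "H")
  has <- c(nrow(h_adp) > 0, nrow(h_623) > 0, nrow(h_624) > 0, has_his)
  failed <- c("no_adp", "no_ps00623", "no_ps00624", "no_catalytic_his")[!has]
  data.frame(seq_id = seq_id,
             has_adp = has[1], has_ps00623 = has[2], has_ps00624 = has[3],
             has_catalytic_his = has[4],
             retained = all(has),
             reason = if (all(has)) "" else paste(failed, collapse = ";"),
             adp_start = if (nrow(h_adp)) h_adp$start[1] else NA_integer_,
             ps00623_start = if (nrow(h_623)) h_623$start[1] else NA_integer_,
             ps00624_start = if (nrow(h_624)) h_624$start[1] else NA_integer_,
             cat1_query_pos = anc$catalytic$query_pos[1],
             cat2_query_pos = anc$catalytic$query_pos[2],
             stringsAsFactors = FALSE)
}

#' Full candidate-selection procedure
#'
#' Composes the two predicates of the screening protocol: a sequence is
#' retained when it passes the homology-hit thresholds (if it has hits at
#' all) AND displays all four conserved features.  Sequences absent from
#' the hit table are screened on features alone and flagged
#' `no_hit_evidence` rather than silently dropped.  A full per-sequence
#' audit report is returned alongside the retained set.
#'
#' @param seqs Named character vector of candidate sequences.
#' @param hit_table Optional hit table data frame (NULL for feature-only
#'   screening).
#' @param anchors Named list of [reference_anchor()] objects by kingdom.
#' @param kingdoms Optional kingdom hints (named by sequence id, or
#'   vector recycled over sequences); `NA` entries are routed to the
#'   best-scoring anchor.
#' @param patterns,windows,params See [check_features()].
#' @param min_identity,max_evalue See [filter_hits()].
#' @return List with `retained` (named character vector) and `report`
#'   (data frame: one row per input sequence; `|report| == |input|`).
#' @export
select_candidates <- function(seqs, hit_table = NULL, anchors,
                              kingdoms = NULL,
                              patterns = aao_signatures(),
                              windows = region_windows(),
                              params = align_params(),
                              min_identity = 35.0, max_evalue = 1e-10) {
  ids <- names(seqs)
  if (length(seqs) == 0L) {
    return(list(retained = setNames(character(0), character(0)),
                report = data.frame()))
  }
  if (is.null(ids) || any(!nzchar(ids)))
    stop_bad("all sequences must be named")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_bad("duplicate sequence ids: ", paste(dup, collapse = ", "))

  hints <- rep(NA_character_, length(seqs))
  if (!is.null(kingdoms)) {
    hints <- if (!is.null(names(kingdoms))) unname(kingdoms[ids])
             else rep_len(kingdoms, length(seqs))
  }

  hit_pass_ids <- character(0)
  hit_subjects <- character(0)
  if (!is.null(hit_table) && nrow(hit_table)) {
    hit_subjects <- unique(hit_table$subject_id)
    hit_pass_ids <- filter_hits(hit_table, min_identity, max_evalue)
  }

  rows <- lapply(seq_along(seqs), function(i) {
    kd <- route_kingdom(seqs[[i]], anchors, hints[i], params = params)
    fr <- check_features(seqs[[i]], ids[i], anchors[[kd]],
                         patterns = patterns, windows = windows,
                         params = params)
    has_hits <- ids[i] %in% hit_subjects
    hit_pass <- if (has_hits) ids[i] %in% hit_pass_ids else NA
    retained <- fr$retained && (is.na(hit_pass) || hit_pass)
    reason <- fr$reason
    if (!is.na(hit_pass) && !hit_pass)
      reason <- paste(c(reason[nzchar(reason)], "hit_thresholds"),
                      collapse = ";")
    cbind(fr[, "seq_id", drop = FALSE],
          data.frame(kingdom = kd, stringsAsFactors = FALSE),
          fr[, setdiff(colnames(fr), c("seq_id", "retained", "reason"))],
          data.frame(no_hit_evidence = !has_hits,
                     hit_pass = hit_pass,
                     retained = retained,
                     reason = reason,
                     stringsAsFactors = FALSE))
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(retained = seqs[report$retained], report = report)
}

#' Write a feature/audit report as TSV
#' @param report Data frame from [select_candidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# feature report; motif starts 0-based,",
                   "mapped catalytic positions 1-based"), con)
  suppressWarnings(
    utils::write.table(report, con, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  invisible(path)
}
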