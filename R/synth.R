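# Synthetic GMC-like protein families with known ground truth.
#
# Every non-decoy sequence carries, at fixed layout positions scaled with
# sequence length: the ADP-binding motif near the N-terminus, a PS00623
# instance in the N-terminal region, a PS00624 instance in the central
# portion, histidines at the two catalytic anchor positions, and
# type-defining residues at the two typing positions.  Decoys ablate
# exactly one feature.  All planted features and typing/catalytic
# positions are protected from background mutation, so ground-truth
# labels survive any mutation rate.

#' Synthetic family configuration
#'
#' @param n_per_type Sequences per (kingdom, type) cell (>= 0).
#' @param seq_length Residues per sequence (>= 200, so all planted
#'   features fit without overlap; default 560, a typical GMC length).
#' @param mutation_rate Per-site substitution probability in [0, 1)
#'   applied outside protected positions.
#' @param seed Integer RNG seed.
#' @param kingdoms Subset of `c("fungi", "bacteria", "arthropod")`.
#' @param type_divergence Per-site substitution probability separating the
#'   founder of each type from the kingdom backbone (default 0.1), so
#'   within-type distances stay below between-type distances.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_per_type = 10L, seq_length = 560L,
                         mutation_rate = 0, seed = 1L,
                         kingdoms = KINGDOMS, type_divergence = 0.1) {
  if (n_per_type < 0) stop_bad("n_per_type must be >= 0")
  if (seq_length < 200) stop_bad("seq_length must be >= 200")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop_bad("mutation_rate must lie in [0, 1)")
  if (type_divergence < 0 || type_divergence >= 1)
    stop_bad("type_divergence must lie in [0, 1)")
  if (!length(kingdoms) || !all(kingdoms %in% KINGDOMS))
    stop_bad("kingdoms must be a subset of ",
             paste(KINGDOMS, collapse = "/"))
  structure(list(n_per_type = as.integer(n_per_type),
                 seq_length = as.integer(seq_length),
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed),
                 kingdoms = KINGDOMS[KINGDOMS %in% kingdoms],
                 type_divergence = type_divergence),
            class = "synth_config")
}

# fixed feature layout for a given sequence length; intervals are 0-based
# half-open (widths follow the fixed signature spans), point positions
# 1-based.  Proportions mirror the PeAAO landmarks (Y92/F501/H502/H546 of
# ~593 residues).
feature_layout <- function(L, patterns = aao_signatures()) {
  lay <- list(
    adp = c(5L, 5L + patterns$adp$min_span),
    typing_a = as.integer(round(0.16 * L)),
    ps00623 = c(as.integer(round(0.18 * L)),
                as.integer(round(0.18 * L)) + patterns$ps00623$min_span),
    ps00624 = c(as.integer(round(0.50 * L)),
                as.integer(round(0.50 * L)) + patterns$ps00624$min_span),
    typing_b = as.integer(round(0.85 * L)) - 1L,
    cat1 = as.integer(round(0.85 * L)),
    cat2 = as.integer(round(0.93 * L)))
  lay$protected <- sort(unique(c(
    (lay$adp[1] + 1L):lay$adp[2],
    (lay$ps00623[1] + 1L):lay$ps00623[2],
    (lay$ps00624[1] + 1L):lay$ps00624[2],
    lay$typing_a, lay$typing_b, lay$cat1, lay$cat2)))
  lay
}

# sample one concrete instance of a pattern (uniform over allowed
# residues; range repeats sample a width uniformly)
sample_pattern_instance <- function(pattern) {
  out <- character(0)
  for (e in pattern$elements) {
    w <- if (e$max_rep > e$min_rep) sample(e$min_rep:e$max_rep, 1) else e$min_rep
    allowed <- switch(e$type,
                      any = AA20,
                      set = e$residues,
                      not = setdiff(AA20, e$residues))
    out <- c(out, sample(allowed, w, replace = TRUE))
  }
  out
}

# allowed typing residues (position a, position b) per kingdom and type;
# weights encode "predominantly" wording where applicable
typing_residue_sets <- function(kingdom, type) {
  arom <- AA_CLASSES$AROMATIC
  alip_polar <- c(AA_CLASSES$ALIPHATIC, AA_CLASSES$UNCHARGED_POLAR)
  if (kingdom == "fungi") {
    switch(type,
      I   = list(a = arom, b = arom),
      II  = list(a = alip_polar, b = arom),
      III = list(a = "G", b = alip_polar))
  } else if (kingdom == "bacteria") {
    switch(type,
      I   = list(a = c("A", "G"), b = "Y"),
      II  = list(a = c("F", "Y"), a_w = c(0.8, 0.2), b = "F"),
      III = list(a = c("V", "L", "I", "M"), b = c("Y", "F")))
  } else {
    list(a = arom, a_w = c(0.1, 0.1, 0.8),          # predominantly Y
         b = c("Y", "K", "R", "H"), b_w = c(0.7, 0.1, 0.1, 0.1))
  }
}

# canonical reference typing residues per kingdom (PeAAO-, ShAAO- and
# CpAAO-like)
reference_typing <- list(fungi = c("Y", "F"),
                         bacteria = c("F", "F"),
                         arthropod = c("Y", "Y"))

kingdom_types <- function(kingdom)
  if (kingdom == "arthropod") "arthropod" else c("I", "II", "III")

sample_weighted <- function(values, weights = NULL) {
  if (length(values) == 1L) return(values)
  sample(values, 1L, prob = weights)
}

mutate_background <- function(chars, rate, protected) {
  if (rate <= 0) return(chars)
  free <- setdiff(seq_along(chars), protected)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  chars
}

build_backbone <- function(L, lay, patterns) {
  chars <- sample(AA20, L, replace = TRUE)
  chars[(lay$adp[1] + 1L):lay$adp[2]] <- sample_pattern_instance(patterns$adp)
  chars[(lay$ps00623[1] + 1L):lay$ps00623[2]] <-
    sample_pattern_instance(patterns$ps00623)
  chars[(lay$ps00624[1] + 1L):lay$ps00624[2]] <-
    sample_pattern_instance(patterns$ps00624)
  chars[c(lay$cat1, lay$cat2)] <- "H"
  chars
}

truth_row <- function(seq_id, kingdom, type, lay, is_decoy = FALSE,
                      ablated = NA_character_) {
  data.frame(seq_id = seq_id, kingdom = kingdom, true_type = type,
             is_decoy = is_decoy, ablated_feature = ablated,
             adp_start = lay$adp[1], adp_end = lay$adp[2],
             ps00623_start = lay$ps00623[1], ps00623_end = lay$ps00623[2],
             ps00624_start = lay$ps00624[1], ps00624_end = lay$ps00624[2],
             typing_a = lay$typing_a, typing_b = lay$typing_b,
             cat1 = lay$cat1, cat2 = lay$cat2,
             stringsAsFactors = FALSE)
}

# generator core; each kingdom block runs under its own derived seed so
# the backbone (and hence the reference anchor) depends only on
# (seed, kingdom), never on how many sequences other cells drew
generate_core <- function(config) {
  patterns <- aao_signatures()
  L <- config$seq_length
  lay <- feature_layout(L, patterns)
  sequences <- character(0)
  truth <- list()
  references <- list()

  for (kingdom in config$kingdoms) {
    kseed <- config$seed + 1009L * match(kingdom, KINGDOMS)
    res <- with_seed(kseed, {
      backbone <- build_backbone(L, lay, patterns)
      ref_chars <- backbone
      ref_chars[c(lay$typing_a, lay$typing_b)] <- reference_typing[[kingdom]]
      ref_id <- paste0("ref_", kingdom)
      anchor <- reference_anchor(
        ref_id, paste(ref_chars, collapse = ""),
        catalytic_positions = c(lay$cat1, lay$cat2),
        typing_positions = c(lay$typing_a, lay$typing_b))

      kseqs <- character(0)
      ktruth <- list()
      for (type in kingdom_types(kingdom)) {
        founder <- mutate_background(backbone, config$type_divergence,
                                     lay$protected)
        sets <- typing_residue_sets(kingdom, type)
        for (i in seq_len(config$n_per_type)) {
          chars <- founder
          # each member draws its own motif instances, so logo columns
          # show the signature's conservation pattern (fixed residues
          # invariant, wildcards variable) instead of a single clone
          chars[(lay$adp[1] + 1L):lay$adp[2]] <-
            sample_pattern_instance(patterns$adp)
          chars[(lay$ps00623[1] + 1L):lay$ps00623[2]] <-
            sample_pattern_instance(patterns$ps00623)
          chars[(lay$ps00624[1] + 1L):lay$ps00624[2]] <-
            sample_pattern_instance(patterns$ps00624)
          chars[lay$typing_a] <- sample_weighted(sets$a, sets$a_w)
          chars[lay$typing_b] <- sample_weighted(sets$b, sets$b_w)
          chars <- mutate_background(chars, config$mutation_rate,
                                     lay$protected)
          id <- sprintf("%s_%s_%03d", kingdom, type, i)
          kseqs[[id]] <- paste(chars, collapse = "")
          ktruth[[id]] <- truth_row(id, kingdom, type, lay)
        }
      }
      list(anchor = anchor, seqs = kseqs, truth = ktruth)
    })
    references[[kingdom]] <- res$anchor
    sequences <- c(sequences, res$seqs)
    truth <- c(truth, res$truth)
  }
  list(sequences = unlist(sequences),
       truth = if (length(truth)) do.call(rbind, c(truth,
                                                   make.row.names = FALSE))
               else data.frame(),
       references = references,
       layout = lay)
}

#' Generate a synthetic GMC-like protein family with ground truth
#'
#' Produces, per (kingdom, type) cell, `n_per_type` sequences carrying
#' all conserved AAO features, along with per-kingdom reference anchors
#' (the unmutated backbones with canonical typing residues) and a truth
#' table.  Identical configurations give byte-identical output.
#'
#' @param config A [synth_config()].
#' @return List with `sequences` (named character vector), `truth` (data
#'   frame of TruthRecords), `references` (named list of
#'   [reference_anchor()] by kingdom) and `layout` (the planted feature
#'   coordinates).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_core(config))
}

SYNTH_FEATURES <- c("adp", "ps00623", "ps00624", "catalytic_his")

# 0-based offsets of the residue-constrained positions of a pattern
# (within a leftmost-shortest match) and the allowed set at each
constrained_offsets <- function(pattern) {
  off <- 0L
  out <- list()
  for (e in pattern$elements) {
    if (e$type %in% c("set", "not")) {
      allowed <- if (e$type == "set") e$residues
                 else setdiff(AA20, e$residues)
      for (k in seq_len(e$min_rep))
        out[[length(out) + 1L]] <- list(off = off + k - 1L,
                                        allowed = allowed)
    }
    off <- off + e$min_rep
  }
  out
}

# replace the planted instance with background residues, then verify by
# rescanning that no match survives anywhere in the sequence; chance
# background matches (possible: the ADP fingerprint constrains only four
# positions) are destroyed by flipping one constrained position inside
# the match to a disallowed residue, avoiding other planted features
ablate_motif <- function(chars, iv, pattern, keep_out = integer(0)) {
  chars[(iv[1] + 1L):iv[2]] <- sample(AA20, iv[2] - iv[1], replace = TRUE)
  cons <- constrained_offsets(pattern)
  for (round in 1:100) {
    hits <- scan_motif(pattern, paste(chars, collapse = ""))
    if (nrow(hits) == 0L) return(chars)
    flipped <- FALSE
    for (cand in cons) {
      pos <- hits$start[1] + cand$off + 1L
      if (!pos %in% keep_out) {
        chars[pos] <- sample(setdiff(AA20, cand$allowed), 1L)
        flipped <- TRUE
        break
      }
    }
    if (!flipped)
      stop_bad("residual motif match lies entirely inside protected ",
               "positions; cannot ablate")
  }
  stop_bad("could not ablate motif without residual matches")
}

#' Generate single-ablation decoys
#'
#' Each decoy is the paired non-decoy from [generate_family()] with
#' exactly one feature ablated: `catalytic_his` substitutes both anchored
#' histidines with alanine; motif ablations replace the planted instance
#' with background residues, re-sampled until a rescan of the full decoy
#' finds no match anywhere.
#'
#' @param config A [synth_config()].
#' @param ablate One of `"adp"`, `"ps00623"`, `"ps00624"`,
#'   `"catalytic_his"`.
#' @return Same shape as [generate_family()], with `is_decoy = TRUE` and
#'   `ablated_feature` set in the truth table.
#' @export
generate_decoys <- function(config, ablate) {
  stopifnot(inherits(config, "synth_config"))
  if (!ablate %in% SYNTH_FEATURES)
    stop_bad("unknown feature '", ablate, "' (expected one of ",
             paste(SYNTH_FEATURES, collapse = ", "), ")")
  fam <- generate_family(config)
  patterns <- aao_signatures()
  lay <- fam$layout
  feat_i <- match(ablate, SYNTH_FEATURES)

  out <- with_seed(config$seed + 7919L * feat_i, {
    seqs <- fam$sequences
    for (k in seq_along(seqs)) {
      chars <- seq_chars(seqs[[k]])
      if (ablate == "catalytic_his") {
        chars[c(lay$cat1, lay$cat2)] <- "A"
      } else {
        iv <- lay[[ablate]]
        keep_out <- setdiff(lay$protected, (iv[1] + 1L):iv[2])
        chars <- ablate_motif(chars, iv, patterns[[ablate]], keep_out)
      }
      seqs[[k]] <- paste(chars, collapse = "")
    }
    seqs
  })

  ids <- paste0(names(out), "_decoy_", ablate)
  names(out) <- ids
  truth <- fam$truth
  truth$seq_id <- ids
  truth$is_decoy <- TRUE
  truth$ablated_feature <- ablate
  list(sequences = out, truth = truth,
       references = fam$references, layout = lay)
}

#' Generate a 12-column tabular hit table with given identities/e-values
#'
#' One row per subject id; the remaining tabular fields are filled with
#' deterministic seeded values consistent with the identities.
#'
#' @param ids Subject identifiers.
#' @param identity_values Percent identities (same length as `ids`).
#' @param evalues E-values (same length as `ids`).
#' @param query_id Query identifier for all rows.
#' @param seed RNG seed for filler fields.
#' @return Data frame with the 12 standard columns.
#' @export
generate_hit_table <- function(ids, identity_values, evalues,
                               query_id = "query", seed = 1L) {
  if (length(identity_values) != length(ids) ||
      length(evalues) != length(ids))
    stop_bad("ids, identity_values and evalues must have equal length")
  n <- length(ids)
  if (n == 0L)
    return(as.data.frame(setNames(rep(list(character(0)), 12),
                                  HIT_COLUMNS)))
  with_seed(seed, {
    alen <- sample(400:600, n, replace = TRUE)
    mism <- pmax(0L, as.integer(round(alen * (1 - identity_values / 100))))
    data.frame(query_id = query_id, subject_id = ids,
               percent_identity = identity_values,
               alignment_length = alen, mismatches = mism,
               gap_opens = 0L, q_start = 1L, q_end = alen,
               s_start = 1L, s_end = alen, evalue = evalues,
               bit_score = round(alen * identity_values / 100 * 2.1, 1),
               stringsAsFactors = FALSE)
  })
}

#' Write a truth table as TSV
#'
#' Planted intervals are encoded as `feature:start-end` triplets (0-based
#' half-open) in a `planted` column alongside the flat columns.
#'
#' @param truth Truth data frame from [generate_family()] /
#'   [generate_decoys()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  t2 <- truth
  t2$planted <- sprintf("adp:%d-%d;ps00623:%d-%d;ps00624:%d-%d",
                        truth$adp_start, truth$adp_end,
                        truth$ps00623_start, truth$ps00623_end,
                        truth$ps00624_start, truth$ps00624_end)
  utils::write.table(t2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic bundle to disk
#'
#' Emits candidate sequences (family plus one decoy set per feature),
#' truth table, a passing hit table, per-kingdom reference FASTA, an
#' anchors YAML and a kingdom-hint TSV — everything [run_pipeline()]
#' needs.
#'
#' @param config A [synth_config()] for the true family.
#' @param dir Output directory (created if needed).
#' @param decoy_n_per_type Decoys per (kingdom, type, feature) cell
#'   (default 1).
#' @return Named list of written file paths plus the in-memory bundle.
#' @export
write_synthetic_bundle <- function(config, dir, decoy_n_per_type = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- generate_family(config)
  dcfg <- synth_config(n_per_type = decoy_n_per_type,
                       seq_length = config$seq_length,
                       mutation_rate = config$mutation_rate,
                       seed = config$seed,
                       kingdoms = config$kingdoms,
                       type_divergence = config$type_divergence)
  decoys <- lapply(SYNTH_FEATURES, function(f) generate_decoys(dcfg, f))
  seqs <- c(fam$sequences, unlist(lapply(decoys, `[[`, "sequences")))
  truth <- do.call(rbind, c(list(fam$truth),
                            lapply(decoys, `[[`, "truth")))

  paths <- list(
    sequences = file.path(dir, "sequences.fasta"),
    truth = file.path(dir, "truth.tsv"),
    hits = file.path(dir, "hits.tsv"),
    references = file.path(dir, "references.fasta"),
    anchors = file.path(dir, "anchors.yaml"),
    kingdoms = file.path(dir, "kingdoms.tsv"))

  write_fasta(seqs, paths$sequences)
  write_truth_table(truth, paths$truth)
  hits <- with_seed(config$seed + 13L, generate_hit_table(
    names(seqs),
    identity_values = round(stats::runif(length(seqs), 40, 90), 1),
    evalues = 10^(-stats::runif(length(seqs), 20, 60)),
    seed = config$seed + 17L))
  write_hit_table(hits, paths$hits)

  refs <- setNames(
    vapply(fam$references, `[[`, "", "sequence"),
    vapply(fam$references, `[[`, "", "reference_id"))
  write_fasta(refs, paths$references)
  anchors_yaml <- lapply(fam$references, function(an) {
    list(id = an$reference_id,
         catalytic = as.list(an$catalytic_positions),
         typing = as.list(an$typing_positions))
  })
  yaml::write_yaml(anchors_yaml, paths$anchors)
  utils::write.table(
    data.frame(seq_id = truth$seq_id, kingdom = truth$kingdom),
    paths$kingdoms, sep = "\t", quote = FALSE, row.names = FALSE)

  c(paths, list(family = fam, decoys = decoys, truth_table = truth,
                sequences_mem = seqs))
}
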