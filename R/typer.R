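# Kingdom-specific active-site typing rules.
#
# Typing reads two active-site positions located by reference anchoring:
# position a (the PeAAO Y92 equivalent: ShAAO F92 in bacteria, CpAAO Y128
# in arthropods) is the primary classifier; position b (the PeAAO F501
# equivalent: ShAAO F455, CpAAO Y535) only sets a consistency flag --
# per-type residue distributions are described at b, not a second
# independent rule.  Rules are ordered so class overlaps resolve
# deterministically (e.g. bacterial A/G is claimed by type I before the
# aliphatic test for type III).

UNMAPPED_LABEL <- "unclassified"

.call <- function(label, consistency, rule_id)
  list(label = label, consistency = consistency, rule_id = rule_id)

#' Classify a fungal AAO from its two active-site residues
#'
#' Typing by the aromaticity of the PeAAO Y92-equivalent residue:
#' aromatic (F/W/Y) gives type I (the classical Basidiomycota AAOs such
#' as PeAAO itself); glycine gives type III (the MtAAO / Ascomycota
#' group); aliphatic or uncharged polar residues give type II.  At the
#' F501-equivalent position, types I and II are expected to retain an
#' aromatic residue while type III is expected to have lost aromaticity;
#' a mismatch clears the consistency flag without changing the label.
#'
#' @param residue_a,residue_b One-letter residue codes at the two typing
#'   positions, or `NA` for unmapped.
#' @return List with `label` (`"I"`, `"II"`, `"III"`, `"ambiguous"` or
#'   `"unclassified"`), `consistency` (logical or NA) and `rule_id`.
#' @export
classify_fungal <- function(residue_a, residue_b) {
  if (is.na(residue_a) || is.na(residue_b))
    return(.call(UNMAPPED_LABEL, NA, "fungal_unmapped"))
  arom <- AA_CLASSES$AROMATIC
  if (residue_a %in% arom)
    return(.call("I", residue_b %in% arom, "fungal_I_aromatic"))
  if (residue_a == "G")
    return(.call("III", !(residue_b %in% arom), "fungal_III_glycine"))
  if (residue_a %in% c(AA_CLASSES$ALIPHATIC, AA_CLASSES$UNCHARGED_POLAR))
    return(.call("II", residue_b %in% arom, "fungal_II_aliphatic_polar"))
  .call("ambiguous", NA, "fungal_fallback")
}

#' Classify a bacterial AAO from its two active-site residues
#'
#' Ordered rules on the ShAAO F92-equivalent residue: alanine or glycine
#' gives type I; phenylalanine gives type II (tyrosine is admitted
#' alongside, covering the Geminicoccaceae variant); the remaining
#' aliphatic residues (V/L/I/M) give type III.  Expected residues at the
#' F455-equivalent position: Y for type I, F for type II, Y or F for type
#' III.  ShAAO (F, F) types as II and SdAAO (V, F) as III.
#'
#' @inheritParams classify_fungal
#' @return Same shape as [classify_fungal()].
#' @export
classify_bacterial <- function(residue_a, residue_b) {
  if (is.na(residue_a) || is.na(residue_b))
    return(.call(UNMAPPED_LABEL, NA, "bacterial_unmapped"))
  if (residue_a %in% c("A", "G"))
    return(.call("I", residue_b == "Y", "bacterial_I_ala_gly"))
  if (residue_a %in% c("F", "Y"))
    return(.call("II", residue_b == "F", "bacterial_II_phe"))
  if (residue_a %in% c("V", "L", "I", "M"))
    return(.call("III", residue_b %in% c("Y", "F"), "bacterial_III_aliphatic"))
  .call("ambiguous", NA, "bacterial_fallback")
}

#' Classify an arthropod AAO from its two active-site residues
#'
#' Arthropod AAOs form a single type with a conserved aromatic residue at
#' the CpAAO Y128-equivalent position; at the Y535-equivalent position
#' they predominantly carry tyrosine or occasionally positively charged
#' residues, which sets the consistency flag.
#'
#' @inheritParams classify_fungal
#' @return Same shape as [classify_fungal()]; label is `"arthropod"`,
#'   `"ambiguous"` or `"unclassified"`.
#' @export
classify_arthropod <- function(residue_a, residue_b) {
  if (is.na(residue_a) || is.na(residue_b))
    return(.call(UNMAPPED_LABEL, NA, "arthropod_unmapped"))
  if (residue_a %in% AA_CLASSES$AROMATIC) {
    ok <- residue_b == "Y" || residue_b %in% AA_CLASSES$POSITIVE
    return(.call("arthropod", ok, "arthropod_aromatic"))
  }
  .call("ambiguous", NA, "arthropod_fallback")
}

kingdom_classifier <- function(kingdom) {
  switch(kingdom,
         fungi = classify_fungal,
         bacteria = classify_bacterial,
         arthropod = classify_arthropod,
         stop_bad("unknown kingdom '", kingdom, "'"))
}

#' Type one sequence against its kingdom's reference anchor
#'
#' Aligns the query to the reference, maps the two typing positions and
#' dispatches to the kingdom rule.  A gap at either typing position gives
#' the label `"unclassified"`.
#'
#' @param seq Query sequence (string).
#' @param seq_id Query identifier.
#' @param kingdom `"fungi"`, `"bacteria"` or `"arthropod"`.
#' @param anchor The kingdom's [reference_anchor()].
#' @param params [align_params()].
#' @return One-row data frame (a TypeCall): `seq_id`, `kingdom`, `label`,
#'   `residue_a`, `residue_b`, `rule_id`, `consistency`.
#' @export
classify_record <- function(seq, seq_id, kingdom, anchor,
                            params = align_params()) {
  cls <- kingdom_classifier(kingdom)
  anc <- anchor_query(seq, seq_id, anchor, params = params)
  ra <- anc$typing$query_residue[1]
  rb <- anc$typing$query_residue[2]
  res <- cls(ra, rb)
  data.frame(seq_id = seq_id, kingdom = kingdom, label = res$label,
             residue_a = ifelse(is.na(ra), NA_character_, ra),
             residue_b = ifelse(is.na(rb), NA_character_, rb),
             rule_id = res$rule_id, consistency = res$consistency,
             stringsAsFactors = FALSE)
}

#' Type a batch of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param kingdoms Character vector (recycled or named by sequence id) of
#'   kingdom hints; `NA` entries are routed to the best-scoring anchor.
#' @param anchors Named list of [reference_anchor()] objects, one per
#'   kingdom.
#' @param params [align_params()].
#' @return Data frame of TypeCalls, one row per input sequence, in input
#'   order.
#' @export
classify_batch <- function(seqs, kingdoms = NULL, anchors,
                           params = align_params()) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop_bad("sequences must have unique names")
  hints <- rep(NA_character_, length(seqs))
  if (!is.null(kingdoms)) {
    hints <- if (!is.null(names(kingdoms))) {
      unname(kingdoms[ids])
    } else rep_len(kingdoms, length(seqs))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    kd <- route_kingdom(seqs[[i]], anchors, hints[i], params = params)
    classify_record(seqs[[i]], ids[i], kd, anchors[[kd]], params = params)
  })
  do.call(rbind, rows)
}

#' Per-type counts of a batch of TypeCalls
#'
#' @param calls Data frame from [classify_batch()].
#' @return Nested list (kingdom -> label -> count), convenient for JSON
#'   serialisation.
#' @export
type_counts <- function(calls) {
  out <- list()
  for (kd in sort(unique(calls$kingdom))) {
    sub <- calls[calls$kingdom == kd, ]
    tab <- table(sub$label)
    out[[kd]] <- as.list(setNames(as.integer(tab), names(tab)))
  }
  out
}
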