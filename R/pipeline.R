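# Pipeline orchestration: screen -> type -> logo -> phylogeny, with
# machine-readable reports and a run manifest.

PIPELINE_KEYS <- c("sequences", "hit_table", "msa", "references_fasta",
                   "anchors", "kingdoms", "signatures",
                   "min_identity", "max_evalue",
                   "nterm_frac", "central_frac",
                   "logo_correction", "phylo_correction", "outgroup",
                   "outdir", "seed")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list.  Unknown keys, missing input
#' files and non-positive thresholds are rejected with an aggregated
#' message; defaults are filled in for everything optional.
#'
#' Required keys: `sequences` (FASTA), `references_fasta` (per-kingdom
#' reference FASTA) and `anchors` (YAML mapping kingdom to `id`,
#' `catalytic` and `typing` position lists), and `outdir`.  Optional:
#' `hit_table` (12-column tabular), `kingdoms` (TSV seq_id/kingdom),
#' `msa` (aligned FASTA used instead of the built-in progressive
#' aligner), `signatures` (id<TAB>pattern file), thresholds and window
#' fractions, `phylo_correction` (`"none"`/`"poisson"`), `outgroup`
#' (leaf ids), `seed`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_bad("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_bad("config must be a list or a YAML path")
  problems <- character(0)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  for (key in c("sequences", "references_fasta", "anchors")) {
    if (is.null(config[[key]]))
      problems <- c(problems, paste0("missing required key '", key, "'"))
  }
  for (key in c("sequences", "hit_table", "msa", "references_fasta",
                "anchors", "kingdoms", "signatures")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      problems <- c(problems, paste0(key, ": file not found: ", p))
  }
  defaults <- list(min_identity = 35.0, max_evalue = 1e-10,
                   nterm_frac = 0.4, central_frac = c(0.3, 0.75),
                   logo_correction = "auto", phylo_correction = "none",
                   outgroup = character(0), seed = 1L)
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  if (config$min_identity <= 0)
    problems <- c(problems, "min_identity must be positive")
  if (config$max_evalue <= 0)
    problems <- c(problems, "max_evalue must be positive")
  if (!config$phylo_correction %in% c("none", "poisson"))
    problems <- c(problems, "phylo_correction must be 'none' or 'poisson'")
  if (is.null(config$outdir))
    problems <- c(problems, "missing required key 'outdir'")
  if (length(problems))
    stop_bad("invalid pipeline config:\n  - ",
             paste(problems, collapse = "\n  - "))
  structure(config, class = "pipeline_config")
}

read_anchors_yaml <- function(path, references) {
  raw <- yaml::read_yaml(path)
  anchors <- list()
  for (kd in names(raw)) {
    a <- raw[[kd]]
    if (!a$id %in% names(references))
      stop_bad("anchor reference '", a$id, "' not in references FASTA")
    anchors[[kd]] <- reference_anchor(
      a$id, references[[a$id]],
      catalytic_positions = unlist(a$catalytic),
      typing_positions = unlist(a$typing))
  }
  anchors
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_bad("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full AAO diversity pipeline
#'
#' Screens the input sequences (homology-hit thresholds plus
#' conserved-feature checks), types the retained candidates against
#' their kingdom reference anchors, computes sequence-logo statistics
#' over the PS00623/PS00624 windows of each kingdom's reference, builds
#' a neighbor-joining tree from alignment p-distances and reports type
#' clade coherence.  All outputs are written under `config$outdir`;
#' reruns with the same config and inputs are byte-identical.
#'
#' Output files: `retained.fasta`, `feature_report.tsv`,
#' `type_calls.tsv`, `type_counts.json`, `logo_<kingdom>_<motif>.tsv`,
#' `distances.tsv`, `tree.nwk`, `monophyly.json`, `summary.json`,
#' `manifest.json`.  Motif coordinates in TSVs are 0-based half-open;
#' TypeCall evidence positions are 1-based.
#'
#' @param config A [validate_config()] result, YAML path or list.
#' @return Invisibly, the summary list (input/retained/rejected counts,
#'   per-kingdom type counts, monophyly report, file paths).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  seqs <- stage("read_sequences", read_fasta(config$sequences))
  refs <- stage("read_references", read_fasta(config$references_fasta))
  anchors <- stage("read_anchors", read_anchors_yaml(config$anchors, refs))
  patterns <- if (!is.null(config$signatures))
    stage("read_signatures", {
      sg <- read_signatures(config$signatures)
      names(sg) <- tolower(names(sg))
      list(adp = sg[["adp_binding"]] %||% sg[["adp"]],
           ps00623 = sg[["ps00623"]], ps00624 = sg[["ps00624"]])
    }) else aao_signatures()
  hit_table <- if (!is.null(config$hit_table))
    stage("read_hit_table", read_hit_table(config$hit_table)) else NULL
  kingdom_map <- if (!is.null(config$kingdoms)) {
    km <- utils::read.delim(config$kingdoms, stringsAsFactors = FALSE)
    setNames(km$kingdom, km$seq_id)
  } else NULL
  windows <- region_windows(config$nterm_frac, config$central_frac)

  summary <- list(seed = config$seed,
                  counts = list(input = length(seqs), retained = 0L,
                                rejected = 0L))
  files <- list()

  if (length(seqs) == 0L) {
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(summary))
  }

  # --- screen ---------------------------------------------------------
  sel <- stage("screen", select_candidates(
    seqs, hit_table, anchors, kingdoms = kingdom_map,
    patterns = patterns, windows = windows,
    min_identity = config$min_identity, max_evalue = config$max_evalue))
  files$feature_report <- write_feature_report(sel$report,
                                               out("feature_report.tsv"))
  files$retained <- write_fasta(sel$retained, out("retained.fasta"))
  summary$counts$retained <- length(sel$retained)
  summary$counts$rejected <- length(seqs) - length(sel$retained)

  if (length(sel$retained) == 0L) {
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(summary))
  }

  # --- type -----------------------------------------------------------
  retained_kingdoms <- setNames(
    sel$report$kingdom[sel$report$retained],
    sel$report$seq_id[sel$report$retained])
  calls <- stage("type", classify_batch(sel$retained,
                                        kingdoms = retained_kingdoms,
                                        anchors = anchors))
  utils::write.table(calls, out("type_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$type_calls <- out("type_calls.tsv")
  summary$type_counts <- type_counts(calls)
  jsonlite::write_json(summary$type_counts, out("type_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # --- align (per kingdom, reference included for numbering) ----------
  ext_msa <- if (!is.null(config$msa))
    stage("read_msa", read_fasta(config$msa)) else NULL

  kingdom_msas <- list()
  for (kd in unique(retained_kingdoms)) {
    members <- names(retained_kingdoms)[retained_kingdoms == kd]
    an <- anchors[[kd]]
    rows <- c(setNames(an$sequence, an$reference_id),
              sel$retained[members])
    kingdom_msas[[kd]] <- stage(paste0("msa_", kd), {
      if (!is.null(ext_msa) && all(names(rows) %in% names(ext_msa)))
        ext_msa[names(rows)]
      else if (length(rows) >= 2L) progressive_msa(rows)
      else NULL
    })
  }

  # --- logos over the reference PS00623/PS00624 windows ---------------
  for (kd in names(kingdom_msas)) {
    msa <- kingdom_msas[[kd]]
    if (is.null(msa)) next
    an <- anchors[[kd]]
    for (motif in c("ps00623", "ps00624")) {
      hit <- scan_motif(patterns[[motif]], an$sequence, an$reference_id)
      if (!nrow(hit)) next
      positions <- (hit$start[1] + 1L):hit$end[1]
      logo <- stage(paste("logo", kd, motif),
                    build_logo(msa, an$reference_id, positions,
                               small_sample_correction =
                                 config$logo_correction))
      f <- out(paste0("logo_", kd, "_", motif, ".tsv"))
      write_logo_tsv(logo, f)
      files[[paste0("logo_", kd, "_", motif)]] <- f
    }
  }

  # --- phylogeny ------------------------------------------------------
  truth_labels <- setNames(paste(calls$kingdom, calls$label, sep = ":"),
                           calls$seq_id)
  if (length(sel$retained) >= 4L) {
    msa_all <- stage("msa_all", {
      if (!is.null(ext_msa) && all(names(sel$retained) %in% names(ext_msa)))
        ext_msa[names(sel$retained)]
      else progressive_msa(sel$retained)
    })
    D <- stage("distances",
               p_distance_matrix(msa_all,
                                 correction = config$phylo_correction))
    files$distances <- write_distance_tsv(D, out("distances.tsv"))
    tree <- stage("tree", neighbor_joining(D))
    rooted <- stage("root", {
      og <- intersect(config$outgroup, tree$tip.label)
      if (length(og)) root_with_outgroup(tree, og)
      else phangorn::midpoint(tree)
    })
    ape::write.tree(rooted, out("tree.nwk"))
    files$tree <- out("tree.nwk")
    mono <- stage("monophyly",
                  monophyly_report(rooted,
                                   truth_labels[rooted$tip.label]))
    jsonlite::write_json(mono, out("monophyly.json"), pretty = TRUE,
                         digits = NA)
    files$monophyly <- out("monophyly.json")
    summary$monophyly <- mono
  }

  # --- manifest + summary --------------------------------------------
  manifest <- list(
    package = "aaoscan",
    version = as.character(utils::packageVersion("aaoscan")),
    seed = config$seed,
    inputs = config[intersect(names(config),
                              c("sequences", "hit_table", "msa",
                                "references_fasta", "anchors", "kingdoms",
                                "signatures"))],
    settings = config[intersect(names(config),
                                c("min_identity", "max_evalue",
                                  "nterm_frac", "central_frac",
                                  "logo_correction", "phylo_correction",
                                  "outgroup"))],
    coordinate_conventions = list(
      motif_tsv = "0-based half-open",
      type_call_positions = "1-based residue numbers"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  summary$files <- lapply(files, function(f) basename(as.character(f)))
  jsonlite::write_json(summary[setdiff(names(summary), "monophyly")],
                       out("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
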