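test_that("synth_config validates its invariants", {
  expect_error(synth_config(n_per_type = -1), "n_per_type")
  expect_error(synth_config(seq_length = 150), "seq_length")
  expect_error(synth_config(mutation_rate = 1), "mutation_rate")
  expect_error(synth_config(mutation_rate = -0.1), "mutation_rate")
  expect_error(synth_config(kingdoms = "plants"), "kingdoms")
  expect_s3_class(synth_config(), "synth_config")
})

test_that("generation is seeded and byte-identical across runs", {
  cfg <- synth_config(n_per_type = 2, mutation_rate = 0.15, seed = 7)
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1, f2)
  p1 <- tempfile(); p2 <- tempfile()
  write_fasta(f1$sequences, p1)
  write_fasta(f2$sequences, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a different seed changes the sequences
  f3 <- generate_family(synth_config(n_per_type = 2, mutation_rate = 0.15,
                                     seed = 8))
  expect_false(identical(f1$sequences, f3$sequences))
})

test_that("planted features are found at exactly their planted coordinates", {
  sig <- aao_signatures()
  fam <- generate_family(synth_config(n_per_type = 1, mutation_rate = 0,
                                      seed = 1))
  for (i in seq_len(nrow(fam$truth))) {
    s <- fam$sequences[[fam$truth$seq_id[i]]]
    tr <- fam$truth[i, ]
    expect_true(tr$adp_start %in% scan_motif(sig$adp, s)$start)
    expect_true(tr$ps00623_start %in% scan_motif(sig$ps00623, s)$start)
    expect_true(tr$ps00624_start %in% scan_motif(sig$ps00624, s)$start)
    ch <- strsplit(s, "")[[1]]
    expect_equal(ch[c(tr$cat1, tr$cat2)], c("H", "H"))
  }
})

test_that("protected positions survive heavy mutation", {
  sig <- aao_signatures()
  fam <- generate_family(synth_config(n_per_type = 50, mutation_rate = 0.2,
                                      seed = 3, kingdoms = "fungi",
                                      seq_length = 300))
  hit_ok <- vapply(seq_len(nrow(fam$truth)), function(i) {
    s <- fam$sequences[[fam$truth$seq_id[i]]]
    tr <- fam$truth[i, ]
    tr$adp_start %in% scan_motif(sig$adp, s)$start &&
      tr$ps00623_start %in% scan_motif(sig$ps00623, s)$start &&
      tr$ps00624_start %in% scan_motif(sig$ps00624, s)$start
  }, logical(1))
  expect_equal(mean(hit_ok), 1)   # 100% retention of planted motifs
})

test_that("decoys fail exactly the ablated feature", {
  sig <- aao_signatures()
  cfg <- synth_config(n_per_type = 1, mutation_rate = 0, seed = 9)
  fam <- generate_family(cfg)

  dec <- generate_decoys(cfg, "ps00624")
  for (s in dec$sequences)
    expect_equal(nrow(scan_motif(sig$ps00624, s)), 0)

  dec2 <- generate_decoys(cfg, "catalytic_his")
  for (i in seq_len(nrow(dec2$truth))) {
    ch <- strsplit(dec2$sequences[[i]], "")[[1]]
    expect_equal(ch[c(dec2$truth$cat1[i], dec2$truth$cat2[i])],
                 c("A", "A"))
  }

  # ablating the ADP motif leaves the PS00623/PS00624 hits of the paired
  # non-decoy unchanged
  dec3 <- generate_decoys(cfg, "adp")
  for (i in seq_len(nrow(dec3$truth))) {
    pair_id <- sub("_decoy_adp$", "", dec3$truth$seq_id[i])
    s_dec <- dec3$sequences[[i]]
    s_true <- fam$sequences[[pair_id]]
    expect_equal(nrow(scan_motif(sig$adp, s_dec)), 0)
    expect_equal(scan_motif(sig$ps00623, s_dec)$start,
                 scan_motif(sig$ps00623, s_true)$start)
    expect_equal(scan_motif(sig$ps00624, s_dec)$start,
                 scan_motif(sig$ps00624, s_true)$start)
  }

  expect_error(generate_decoys(cfg, "flavin"), "unknown feature")
})

test_that("hit-table generation enforces matching lengths", {
  tab <- generate_hit_table(c("a", "b"), c(36, 35), c(1e-12, 1e-12))
  expect_equal(nrow(tab), 2)
  expect_equal(filter_hits(tab), "a")
  expect_equal(nrow(generate_hit_table(character(0), numeric(0),
                                       numeric(0))), 0)
  expect_error(generate_hit_table("a", c(1, 2), 1e-12), "equal length")
})

test_that("truth tables and bundles serialise consistently", {
  dir <- tempfile()
  b <- write_synthetic_bundle(synth_config(n_per_type = 1, seed = 5), dir)
  expect_true(all(file.exists(unlist(b[c("sequences", "truth", "hits",
                                         "references", "anchors",
                                         "kingdoms")]))))
  seqs <- read_fasta(b$sequences)
  truth <- read.delim(b$truth, stringsAsFactors = FALSE)
  expect_setequal(names(seqs), truth$seq_id)
  expect_equal(sum(!truth$is_decoy), 7)      # one per (kingdom, type) cell
  expect_equal(sum(truth$is_decoy), 28)      # 7 cells x 4 ablations
  expect_match(truth$planted[1], "^adp:5-30;ps00623:")
  refs <- read_fasta(b$references)
  expect_setequal(names(refs),
                  c("ref_fungi", "ref_bacteria", "ref_arthropod"))
})

test_that("label recovery is perfect on unmutated non-decoys", {
  fam <- generate_family(synth_config(n_per_type = 2, mutation_rate = 0,
                                      seed = 13))
  calls <- classify_batch(fam$sequences,
                          kingdoms = setNames(fam$truth$kingdom,
                                              fam$truth$seq_id),
                          anchors = fam$references)
  expect_equal(calls$label,
               fam$truth$true_type[match(calls$seq_id, fam$truth$seq_id)])
})
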