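test_that("hit filtering applies strict thresholds per hit", {
  tab <- generate_hit_table(c("a", "b"), c(36.0, 35.0), c(1e-12, 1e-12))
  expect_equal(filter_hits(tab), "a")

  tab2 <- generate_hit_table("c", 50, 1e-9)
  expect_equal(filter_hits(tab2), character(0))

  # a subject passes if any of its hits passes
  tab3 <- generate_hit_table(c("s1", "s2", "s3"),
                             c(80, 40, 36), c(1e-9, 1e-11, 1e-12))
  expect_equal(filter_hits(tab3), c("s2", "s3"))
  tab4 <- rbind(tab3, generate_hit_table("s1", 60, 1e-30))
  expect_setequal(filter_hits(tab4), c("s1", "s2", "s3"))

  # exact boundary values are rejected under the strict-inequality rule
  tab5 <- generate_hit_table(c("x", "y"), c(35.0, 40), c(1e-12, 1e-10))
  expect_equal(filter_hits(tab5), character(0))
})

test_that("relaxing thresholds never shrinks the retained set", {
  set.seed(91)
  tab <- generate_hit_table(sprintf("s%02d", 1:40),
                            runif(40, 20, 90), 10^(-runif(40, 5, 30)))
  base <- filter_hits(tab, 35, 1e-10)
  expect_true(all(base %in% filter_hits(tab, 30, 1e-10)))
  expect_true(all(base %in% filter_hits(tab, 35, 1e-8)))
  expect_true(all(filter_hits(tab, 40, 1e-12) %in% base))
})

test_that("hit tables round-trip and parse errors name the row", {
  tab <- generate_hit_table(c("a", "b"), c(50, 60), c(1e-20, 1e-30))
  f <- tempfile()
  write_hit_table(tab, f)
  back <- read_hit_table(f)
  expect_equal(back$subject_id, tab$subject_id)
  expect_equal(back$percent_identity, tab$percent_identity)
  expect_equal(back$evalue, tab$evalue)

  writeLines(c("# comment", "only\tthree\tfields"), f)
  expect_error(read_hit_table(f), "line 2")
  writeLines(paste(c("q", "s", "NOTANUM", rep("1", 9)), collapse = "\t"), f)
  expect_error(read_hit_table(f), "percent_identity")
  writeLines("# nothing", f)
  expect_equal(nrow(read_hit_table(f)), 0)
})

test_that("feature checks pass planted sequences and fail each decoy", {
  fam <- synth_small()
  anchors <- fam$references
  km <- setNames(fam$truth$kingdom, fam$truth$seq_id)

  id <- fam$truth$seq_id[1]
  fr <- check_features(fam$sequences[[id]], id, anchors[[km[[id]]]])
  expect_true(fr$retained)
  expect_true(all(unlist(fr[c("has_adp", "has_ps00623", "has_ps00624",
                              "has_catalytic_his")])))
  expect_equal(fr$adp_start, fam$truth$adp_start[1])
  expect_equal(fr$ps00623_start, fam$truth$ps00623_start[1])
  expect_equal(fr$ps00624_start, fam$truth$ps00624_start[1])

  flags <- c(adp = "has_adp", ps00623 = "has_ps00623",
             ps00624 = "has_ps00624", catalytic_his = "has_catalytic_his")
  dcfg <- synth_config(n_per_type = 1, mutation_rate = 0, seed = 42)
  for (feat in names(flags)) {
    dec <- generate_decoys(dcfg, feat)
    for (i in seq_along(dec$sequences)) {
      kd <- dec$truth$kingdom[i]
      fr <- check_features(dec$sequences[[i]], dec$truth$seq_id[i],
                           anchors[[kd]])
      got <- unlist(fr[unname(flags)])
      expect_false(fr$retained)
      expect_false(got[[flags[[feat]]]])
      expect_true(all(got[setdiff(names(got), flags[[feat]])]))
      expect_match(fr$reason, paste0("no_", feat))
    }
  }
})

test_that("short sequences are reported as too_short, not raised", {
  fam <- synth_small()
  fr <- check_features("ACDEFGHIKL", "tiny", fam$references$fungi)
  expect_false(fr$retained)
  expect_equal(fr$reason, "too_short")
})

test_that("select_candidates composes hit and feature predicates", {
  fam <- generate_family(synth_config(n_per_type = 1, mutation_rate = 0,
                                      seed = 7))
  dec <- generate_decoys(synth_config(n_per_type = 1, mutation_rate = 0,
                                      seed = 7), "ps00623")
  seqs <- c(fam$sequences, dec$sequences)
  km <- setNames(c(fam$truth$kingdom, dec$truth$kingdom),
                 c(fam$truth$seq_id, dec$truth$seq_id))
  hits <- generate_hit_table(names(seqs), rep(70, length(seqs)),
                             rep(1e-30, length(seqs)))
  sel <- select_candidates(seqs, hits, fam$references, kingdoms = km)
  expect_setequal(names(sel$retained), fam$truth$seq_id)
  expect_equal(nrow(sel$report), length(seqs))
  expect_true(all(nzchar(sel$report$reason[!sel$report$retained])))

  # passing features but failing identity -> rejected with the hit reason
  hits2 <- hits
  hits2$percent_identity[hits2$subject_id == fam$truth$seq_id[1]] <- 30
  sel2 <- select_candidates(seqs, hits2, fam$references, kingdoms = km)
  expect_false(fam$truth$seq_id[1] %in% names(sel2$retained))
  r1 <- sel2$report[sel2$report$seq_id == fam$truth$seq_id[1], ]
  expect_match(r1$reason, "hit_thresholds")

  # sequences absent from the hit table are flagged, not dropped
  hits3 <- hits[hits$subject_id != fam$truth$seq_id[2], ]
  sel3 <- select_candidates(seqs, hits3, fam$references, kingdoms = km)
  r2 <- sel3$report[sel3$report$seq_id == fam$truth$seq_id[2], ]
  expect_true(r2$no_hit_evidence)
  expect_true(r2$retained)
})

test_that("select_candidates handles empty input and duplicate ids", {
  fam <- synth_small()
  empty <- select_candidates(setNames(character(0), character(0)),
                             NULL, fam$references)
  expect_length(empty$retained, 0)
  dup <- fam$sequences[c(1, 1)]
  expect_error(select_candidates(dup, NULL, fam$references), "duplicate")
})

test_that("kingdom routing falls back to the best-scoring anchor", {
  fam <- synth_small()
  id <- fam$truth$seq_id[fam$truth$kingdom == "bacteria"][1]
  sel <- select_candidates(fam$sequences[id], NULL, fam$references)
  expect_equal(sel$report$kingdom, "bacteria")
  expect_true(sel$report$retained)
})
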