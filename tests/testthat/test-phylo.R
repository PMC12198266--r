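test_that("p-distances count mismatches over shared ungapped columns", {
  msa <- c(a = strrep("A", 100), b = strrep("A", 100), c = strrep("A", 100))
  expect_true(all(p_distance_matrix(msa) == 0))

  b <- paste0(strrep("C", 5), strrep("A", 95))
  msa2 <- c(a = strrep("A", 100), b = b, c = strrep("A", 100))
  D <- p_distance_matrix(msa2)
  expect_equal(D["a", "b"], 0.05)
  Dp <- p_distance_matrix(msa2, correction = "poisson")
  expect_equal(Dp["a", "b"], -log(0.95), tolerance = 1e-9)
  expect_equal(Dp["a", "b"], 0.051293, tolerance = 1e-5)

  # gapped columns drop out of the denominator
  msa3 <- c(a = "AAAAAAAAAC", b = "----AAAAAA", c = "AAAAAAAAAA")
  D3 <- p_distance_matrix(msa3)
  expect_equal(D3["a", "b"], 1 / 6)

  msa4 <- c(a = "AA--", b = "--AA", c = "AAAA")
  expect_error(p_distance_matrix(msa4), "no shared ungapped")
  msa5 <- c(a = "AAAA", b = "CCCC", c = "AAAA")
  expect_error(p_distance_matrix(msa5, correction = "poisson"),
               "Poisson")
})

test_that("neighbor joining recovers the worked additive example exactly", {
  D <- generate_additive_matrix("((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(D["A", c("B", "C", "D")], c(B = 3, C = 5, D = 6))
  expect_equal(D["B", c("C", "D")], c(C = 6, D = 7))
  expect_equal(D["C", "D"], 7)

  tr <- neighbor_joining(D)
  back <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-12)
  # AB|CD split present
  pp <- ape::prop.part(ape::unroot(tr))
  tipsets <- lapply(pp, function(i) attr(pp, "labels")[i])
  expect_true(any(vapply(tipsets, function(s)
    setequal(s, c("A", "B")) || setequal(s, c("C", "D")), logical(1))))
  # pendant branch lengths recovered exactly
  pend <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  pend <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                        tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("ties break deterministically and negatives are clamped", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  labs <- letters[1:5]
  dimnames(D) <- list(labs, labs)
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
  expect_true(all(neighbor_joining(D)$edge.length >= 0))
})

test_that("NJ exactly recovers random additive matrices", {
  set.seed(37)
  ok <- 0
  for (i in 1:50) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    D <- generate_additive_matrix(ape::write.tree(tr0))
    tr <- neighbor_joining(D)
    back <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_equal(back, D, tolerance = 1e-9)
    # independent cross-check: ape's NJ finds the same topology
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(D)))[1], 0)
    ok <- ok + 1
  }
  expect_equal(ok, 50)
})

test_that("Newick serialisation round-trips trees losslessly", {
  set.seed(43)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:10, 1), br = function(k) runif(k, 0.1, 2))
    back <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(back$edge, tr$edge)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
  }
  expect_error(generate_additive_matrix("((A:1,B:2"), "malformed")
  expect_error(generate_additive_matrix("((A:1,B:-2):1,C:1);"),
               "non-negative")
  expect_error(generate_additive_matrix("(A:1,B:2);"), ">= 3")
  D <- generate_additive_matrix("(A:1,B:1,C:1);")
  expect_true(all(D[upper.tri(D)] == 2))
})

test_that("outgroup rooting splits the separating edge equally", {
  tr <- neighbor_joining(generate_additive_matrix(
    "((A:1,B:2):1,(C:3,D:4):2);"))
  r1 <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(r1))
  root <- length(r1$tip.label) + 1L
  re <- which(r1$edge[, 1] == root)
  expect_equal(r1$edge.length[re[1]], r1$edge.length[re[2]])
  # D's original pendant branch (length 4) is split 2 + 2
  expect_equal(sum(r1$edge.length[re]), 4)

  r2 <- root_with_outgroup(tr, c("C", "D"))
  expect_true(ape::is.rooted(r2))
  og_clade <- ape::extract.clade(
    r2, ape::getMRCA(r2, c("C", "D")))$tip.label
  expect_setequal(og_clade, c("C", "D"))

  expect_error(root_with_outgroup(tr, c("A", "C")), "not monophyletic")
  expect_error(root_with_outgroup(tr, "Z"), "not all present")
})

test_that("monophyly_report matches hand-worked cases", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep1 <- monophyly_report(tr, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(rep1$is_monophyletic))
  expect_true(all(rep1$clade_purity == 1))

  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- monophyly_report(tr2, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_false(any(rep2$is_monophyletic))
  expect_equal(rep2$clade_purity, c(0.5, 0.5))

  rep3 <- monophyly_report(tr, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"))
  expect_true(all(rep3$is_monophyletic[rep3$label %in% c("B", "C")]))

  expect_error(monophyly_report(tr, c(a1 = "A")), "unlabeled")
})

test_that("monophyly_report agrees with a brute-force MRCA oracle", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    labels <- setNames(sample(c("X", "Y", "Z"), n, replace = TRUE),
                       tr$tip.label)
    got <- monophyly_report(tr, labels)
    want <- oracle_monophyly(tr, labels)
    expect_equal(got[, c("label", "is_monophyletic", "clade_purity")],
                 want, tolerance = 1e-12)
  }
})

test_that("synthetic families with coherent types form monophyletic clades", {
  fam <- generate_family(synth_config(n_per_type = 3, mutation_rate = 0.05,
                                      seed = 53))
  msa <- progressive_msa(fam$sequences)
  D <- p_distance_matrix(msa)
  tr <- phangorn::midpoint(neighbor_joining(D))
  labels <- setNames(paste(fam$truth$kingdom, fam$truth$true_type),
                     fam$truth$seq_id)
  rep <- monophyly_report(tr, labels)
  expect_true(all(rep$is_monophyletic))
})
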