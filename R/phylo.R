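# Distance-based phylogeny: p-distances, neighbor joining, outgroup
# rooting and monophyly (clade-coherence) assessment.

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_bad("distance matrix must be square")
  if (is.null(rownames(D)) || anyDuplicated(rownames(D)))
    stop_bad("distance matrix needs unique row/column labels")
  if (!all(is.finite(D))) stop_bad("distance matrix entries must be finite")
  if (any(abs(D - t(D)) > 1e-12)) stop_bad("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 0)) stop_bad("distance matrix diagonal must be zero")
  if (any(D < 0)) stop_bad("distances must be non-negative")
  invisible(TRUE)
}

#' Pairwise p-distances from a multiple alignment
#'
#' p = mismatches / mutually ungapped columns; the Poisson correction is
#' d = -ln(1 - p).  Gap and non-standard characters are excluded from the
#' shared-column count.
#'
#' @param msa Named character vector of equal-length aligned rows (or a
#'   character matrix, one row per sequence).
#' @param correction `"none"` or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (is.matrix(msa)) {
    ids <- rownames(msa)
    M <- msa
  } else {
    ids <- names(msa)
    if (length(unique(nchar(msa))) != 1L)
      stop_bad("alignment rows must have equal length")
    M <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  }
  n <- nrow(M)
  if (n < 3L) stop_bad("need >= 3 aligned sequences")
  ng <- matrix(as.numeric(matrix(M %in% AA20, nrow = n)), nrow = n)
  shared <- ng %*% t(ng)
  matches <- matrix(0, n, n)
  for (r in AA20) {
    I <- matrix(as.numeric(matrix(M == r, nrow = n)), nrow = n)
    matches <- matches + I %*% t(I)
  }
  off <- upper.tri(shared)
  if (any(shared[off] == 0)) {
    w <- which(shared == 0 & off, arr.ind = TRUE)[1, ]
    stop_bad("no shared ungapped columns between '", ids[w[1]],
             "' and '", ids[w[2]], "'")
  }
  p <- (shared - matches) / shared
  diag(p) <- 0
  if (correction == "poisson") {
    if (any(p[off] >= 1)) {
      w <- which(p >= 1 & off, arr.ind = TRUE)[1, ]
      stop_bad("p-distance of 1 between '", ids[w[1]], "' and '",
               ids[w[2]], "': Poisson correction undefined")
    }
    p <- -log(1 - p)
    diag(p) <- 0
  }
  dimnames(p) <- list(ids, ids)
  p
}

#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration with the standard Q criterion and
#' branch-length formulas.  Ties in Q are broken by the lowest (row,
#' column) index pair.  Negative branch-length estimates are clamped to
#' zero with the deficit transferred to the sibling branch.  On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D Labelled symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop_bad("neighbor joining needs >= 3 taxa")
  nodes <- rownames(D)

  fmt <- function(x) sprintf("%.15g", x)
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp2(li, lj)
    newlab <- paste0("(", nodes[i], ":", fmt(ll[1]), ",",
                     nodes[j], ":", fmt(ll[2]), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newlab)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }

  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  nwk <- paste0("(", nodes[1], ":", fmt(l1), ",",
                nodes[2], ":", fmt(l2), ",",
                nodes[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Path-length (additive) distance matrix from a Newick tree
#'
#' Entries are the sums of branch lengths along the unique leaf-to-leaf
#' paths; the result is symmetric with zero diagonal and is exactly
#' recoverable by [neighbor_joining()].
#'
#' @param newick Newick string (branch lengths required, non-negative,
#'   >= 3 leaves).
#' @return Labelled symmetric distance matrix.
#' @export
generate_additive_matrix <- function(newick) {
  tr <- tryCatch(ape::read.tree(text = newick), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop_bad("malformed Newick tree")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop_bad("tree must have branch lengths on every edge")
  if (any(tr$edge.length < 0))
    stop_bad("branch lengths must be non-negative")
  if (length(tr$tip.label) < 3L) stop_bad("tree must have >= 3 leaves")
  D <- ape::cophenetic.phylo(tr)
  D[tr$tip.label, tr$tip.label]
}

#' Root a tree on the edge separating an outgroup
#'
#' The root is placed on the edge separating the outgroup leaves from the
#' ingroup, splitting that branch length equally.  Errors if the outgroup
#' is not separable by a single edge of the unrooted tree.
#'
#' @param tree An `ape::phylo` tree (rooted or not).
#' @param outgroup_ids Character vector of outgroup leaf labels.
#' @return A rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(outgroup_ids %in% tips))
    stop_bad("outgroup ids not all present among leaves")
  if (length(outgroup_ids) == length(tips))
    stop_bad("outgroup cannot contain every leaf")
  utree <- ape::unroot(tree)
  pp <- ape::prop.part(utree)
  is_split <- FALSE
  for (cl in pp) {
    cl_tips <- attr(pp, "labels")[cl]
    if (setequal(cl_tips, outgroup_ids) ||
        setequal(setdiff(tips, cl_tips), outgroup_ids)) {
      is_split <- TRUE
      break
    }
  }
  if (!is_split && length(outgroup_ids) > 1L)
    stop_bad("outgroup not monophyletic in unrooted tree")
  rooted <- ape::root(utree, outgroup = outgroup_ids, resolve.root = TRUE)
  rootnode <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == rootnode)
  if (length(re) == 2L) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- tot / 2
  }
  rooted
}

#' Monophyly (clade-coherence) report for labelled leaves
#'
#' For each label, finds the smallest clade (MRCA subtree) containing all
#' leaves carrying that label.  The label is monophyletic when that clade
#' contains no other leaves; purity is the fraction of clade leaves
#' carrying the label.  Single-member labels are monophyletic by
#' convention.
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param labels Named character vector mapping every leaf label to a type
#'   label.
#' @return Data frame with one row per label: `label`, `n_leaves`,
#'   `clade_size`, `is_monophyletic`, `clade_purity`.
#' @export
monophyly_report <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_bad("tree must be rooted")
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop_bad("unlabeled leaves: ",
             paste(setdiff(tips, names(labels)), collapse = ", "))
  labels <- labels[tips]
  out <- lapply(sort(unique(labels)), function(lab) {
    members <- tips[labels == lab]
    if (length(members) == 1L) {
      return(data.frame(label = lab, n_leaves = 1L, clade_size = 1L,
                        is_monophyletic = TRUE, clade_purity = 1,
                        stringsAsFactors = FALSE))
    }
    mrca <- ape::getMRCA(tree, members)
    clade_tips <- ape::extract.clade(tree, mrca)$tip.label
    data.frame(label = lab,
               n_leaves = length(members),
               clade_size = length(clade_tips),
               is_monophyletic = length(clade_tips) == length(members),
               clade_purity = length(members) / length(clade_tips),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a distance matrix as square TSV (header row and column)
#'
#' @param D Labelled distance matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
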