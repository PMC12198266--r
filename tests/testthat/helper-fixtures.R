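# Shared fixture builders: random sequences, random PROSITE patterns,
# ideal-helix chains and small oracles used across test files.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# random PROSITE-grammar signature text (kept small so the brute-force
# scanner stays fast)
rand_prosite <- function() {
  n_el <- sample(3:6, 1)
  els <- vapply(seq_len(n_el), function(i) {
    core <- switch(sample(3, 1),
                   sample(AA, 1),
                   "x",
                   paste0("[", paste(sample(AA, sample(2:4, 1)),
                                     collapse = ""), "]"))
    rep <- if (runif(1) < 0.3) {
      if (runif(1) < 0.5) paste0("(", sample(2:3, 1), ")")
      else {
        lo <- sample(1:2, 1)
        paste0("(", lo, ",", lo + sample(1:2, 1), ")")
      }
    } else ""
    paste0(core, rep)
  }, character(1))
  paste(els, collapse = "-")
}

# ideal alpha-helix C-alpha trace (2.3 A radius, 1.5 A rise, 100 deg/res)
helix_coords <- function(n) {
  t <- seq_len(n)
  cbind(2.3 * cos(t * 100 * pi / 180), 2.3 * sin(t * 100 * pi / 180),
        1.5 * t)
}

rot_xyz <- function(p) {
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# independent three-state affine-gap DP oracle (scores only)
oracle_align_score <- function(a, b, S, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[A[i], B[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                           Y[i, j + 1] - go - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                           Y[i + 1, j] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force MRCA/monophyly oracle: enumerates every clade's tip set by
# direct recursion over the edge matrix
oracle_monophyly <- function(tree, labels) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc), use.names = FALSE)
  }
  clades <- lapply(c(seq_len(nt), as.integer(names(kids))), desc)
  labs <- sort(unique(labels))
  do.call(rbind, lapply(labs, function(lab) {
    members <- names(labels)[labels == lab]
    sizes <- vapply(clades, function(cl)
      if (all(members %in% cl)) length(cl) else Inf, numeric(1))
    best <- clades[[which.min(sizes)]]
    data.frame(label = lab,
               is_monophyletic = setequal(best, members),
               clade_purity = length(members) / length(best),
               stringsAsFactors = FALSE)
  }))
}

# brute-force rotational search for the minimal RMSD (restarted
# Nelder-Mead over Euler angles, translation solved by centroids)
oracle_min_rmsd <- function(A, B, n_starts = 24) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  f <- function(p) sqrt(mean(rowSums((Ac %*% t(rot_xyz(p)) - Bc)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    r <- stats::optim(stats::runif(3, -pi, pi), f,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

# small synthetic family cached across test files
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_family(synth_config(n_per_type = 2,
                                             mutation_rate = 0, seed = 42))
    cache
  }
})
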