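# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths wherever an external implementation exists.

# Brute-force global affine-gap alignment score (Gotoh three-state DP).
# Convention matched to align_pairwise(): a gap of length L costs
# open + extend * L.
oracle_align_score <- function(query, ref, gap_open = 10, gap_extend = 1,
                               submat = NULL) {
  if (is.null(submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  a <- strsplit(query, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in ref (query residue unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query
  M[1, 1] <- 0
  if (n) X[2:(n + 1), 1] <- -gap_open - gap_extend * seq_len(n)
  if (m) Y[1, 2:(m + 1)] <- -gap_open - gap_extend * seq_len(m)
  for (i in 2:(n + 1)) {
    s_row <- submat[a[i - 1], b]
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        s_row[j - 1]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Random additive (tree-metric) distance matrix: draw a random unrooted
# binary topology with ape, give every edge a positive length, and return
# the implied leaf-to-leaf path-length matrix together with the tree.
oracle_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, rooted = TRUE, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  D <- as.matrix(ape::cophenetic.phylo(tr))
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Robinson-Foulds distance between two unrooted trees (via ape).
oracle_rf <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85")[1]
}

# Gapless toy alignment rows used by several files.
toy_msa <- function() {
  c(a = "ARNDCQEGHILKMFPSTWYV",
    b = "ARNDCQEGHILKMFPSTWYV",
    c = "ARNDCQEGHILKMFPSTWYM",
    d = "GRNDCQEGHILKMFPSTWYM")
}
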