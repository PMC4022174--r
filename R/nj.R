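# Neighbour-joining tree construction (Saitou-Nei agglomeration with the
# Studier-Keppler Q-criterion), bootstrap bipartition supports, monophyly
# queries and Newick input/output. Trees are ape "phylo" objects.

validate_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(D)) || anyDuplicated(rownames(D)) ||
      !identical(rownames(D), colnames(D))) {
    stop("distance matrix needs matching unique row/column names",
         call. = FALSE)
  }
  if (any(!is.finite(D))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  invisible(TRUE)
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining using the Studier-Keppler criterion
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)`. Ties in Q are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster represented by its smallest leaf id, C-locale order), so the
#' construction is fully deterministic. Negative intermediate branch
#' lengths are clamped to zero with the deficit transferred to the
#' sibling edge. On an additive matrix the generating tree is recovered
#' exactly (topology and branch lengths). Three taxa give the unique star
#' with closed-form lengths; four or more distinct taxa give a fully
#' resolved unrooted binary tree.
#'
#' @param D symmetric non-negative matrix with zero diagonal and matching
#'   unique row/column names.
#' @return An unrooted `phylo` tree (package ape).
#' @export
#' @examples
#' D <- matrix(c(0, 3, 7, 8, 3, 0, 8, 9, 7, 8, 0, 5, 8, 9, 5, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(D)
nj_tree <- function(D) {
  validate_dist_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  frag <- rownames(D)        # newick fragment per active cluster
  rep_id <- rownames(D)      # smallest leaf id per active cluster
  W <- D

  while (nrow(W) > 3) {
    m <- nrow(W)
    r <- rowSums(W)
    Q <- (m - 2) * W - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- stable_sort(rep_id[ij])
      paste(p, collapse = "\r")
    })
    pick <- cand[stable_order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- W[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; if (li < 0) li <- 0 }

    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li),
                        frag[j], fmt_len(lj))
    new_rep <- stable_sort(c(rep_id[i], rep_id[j]))[1]
    du <- 0.5 * (W[i, ] + W[j, ] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    W2 <- rbind(cbind(W[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    lbl <- c(rownames(W)[keep], new_rep)
    dimnames(W2) <- list(lbl, lbl)
    W <- W2
    frag <- c(frag[keep], new_frag)
    rep_id <- c(rep_id[keep], new_rep)
  }

  d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  v[v < 0] <- 0
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt_len(v[1]), frag[2], fmt_len(v[2]),
                 frag[3], fmt_len(v[3]))
  ape::read.tree(text = nwk)
}

# canonical key for one leaf set: take the side not containing the
# overall reference leaf, sort in C locale, join
split_key <- function(leaves, all_leaves) {
  ref <- stable_sort(all_leaves)[1]
  side <- if (ref %in% leaves) setdiff(all_leaves, leaves) else leaves
  paste(stable_sort(side), collapse = "\r")
}

# internal-edge bipartitions of a phylo tree: named character vector,
# names = canonical keys, values = node labels (support strings); the
# basal node is excluded
tree_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  nt <- length(labels)
  out <- character(0)
  for (k in seq_along(pp)) {
    node <- nt + k
    if (node == nt + 1L) next          # basal node: not an internal edge
    clade <- labels[pp[[k]]]
    if (length(clade) <= 1L || length(clade) >= nt) next
    key <- split_key(clade, labels)
    val <- if (!is.null(tree$node.label)) tree$node.label[k] else NA_character_
    out[key] <- val %||% NA_character_
  }
  out
}

#' Test a leaf subset for monophyly
#'
#' A leaf set is monophyletic (in the unrooted sense) when some edge
#' bipartition of the tree separates exactly that set from all remaining
#' leaves.
#'
#' @param tree a `phylo` tree.
#' @param labels leaf subset, `2 <= |labels| <` number of leaves.
#' @return `list(monophyletic = logical, support = numeric)`; the support
#'   is the defining internal edge's value (from the node labels written
#'   by [bootstrap_supports()]) or `NA` when absent or when the defining
#'   edge is a pendant-edge complement.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown)) {
    stop(sprintf("unknown leaf label '%s'", unknown[1]), call. = FALSE)
  }
  if (length(labels) < 2 || length(labels) >= length(tips)) {
    stop("labels must name at least 2 and fewer than all leaves",
         call. = FALSE)
  }
  if (length(labels) == length(tips) - 1L) {
    # complement of a single tip: the pendant edge always defines it
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  splits <- tree_splits(tree)
  key <- split_key(labels, tips)
  if (key %in% names(splits)) {
    sup <- suppressWarnings(as.numeric(splits[[key]]))
    list(monophyletic = TRUE, support = sup)
  } else {
    list(monophyletic = FALSE, support = NA_real_)
  }
}

# distance matrix from an integer-coded alignment (rows = taxa, NA = gap)
jtt_dist_from_idx <- function(IA, d_max = 10, tol = 1e-6) {
  model <- jtt_model()
  n <- nrow(IA)
  ids <- rownames(IA)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ka <- IA[i, ]; kb <- IA[j, ]
      keep <- !is.na(ka) & !is.na(kb)
      if (!any(keep)) {
        stop("no shared ungapped columns between two rows", call. = FALSE)
      }
      counts <- matrix(tabulate((ka[keep] - 1L) * 20L + kb[keep],
                                nbins = 400L), nrow = 20L, byrow = TRUE)
      if (sum(counts) == sum(diag(counts))) {
        d <- 0
      } else {
        opt <- stats::optimize(jtt_loglik, interval = c(0, d_max),
                               counts = counts, model = model,
                               maximum = TRUE, tol = tol)
        d <- min(opt$maximum, d_max)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

msa_to_idx <- function(msa) {
  msa <- as_msa(msa)
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  IA <- matrix(match(m, AA20), nrow = nrow(m),
               dimnames = list(names(msa), NULL))
  IA
}

#' Neighbour-joining tree with bootstrap bipartition supports
#'
#' Builds the JTT-distance NJ tree on the full alignment, then resamples
#' alignment columns with replacement (same column count) `n_reps` times,
#' recomputing distances and the NJ tree each time. The support of every
#' internal edge of the full-data tree is the percentage of replicate
#' trees containing the same leaf bipartition, attached as integer node
#' labels. Replicates whose distance matrix is degenerate (a pair with no
#' shared ungapped columns) are recorded and skipped; more than 10\%
#' skips is an error.
#'
#' @param msa alignment coercible via [as_msa()], at least 4 rows.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed; fixed seed gives identical supports.
#' @param d_max,tol passed to the distance estimator.
#' @return The full-data `phylo` tree with `node.label` supports in
#'   `[0, 100]` and attribute `n_effective` (replicates used).
#' @export
bootstrap_supports <- function(msa, n_reps = 1000, seed, d_max = 10,
                               tol = 1e-6) {
  msa <- as_msa(msa)
  if (length(msa) < 4) {
    stop("bootstrap supports need at least 4 taxa", call. = FALSE)
  }
  IA <- msa_to_idx(msa)
  L <- ncol(IA)
  tree0 <- nj_tree(jtt_dist_from_idx(IA, d_max, tol))
  keys0 <- names(tree_splits(tree0))
  counts <- stats::setNames(rep(0L, length(keys0)), keys0)
  skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_tree <- tryCatch(
        nj_tree(jtt_dist_from_idx(IA[, cols, drop = FALSE], d_max, tol)),
        error = function(e) NULL)
      if (is.null(rep_tree)) {
        skipped <- skipped + 1L
        next
      }
      hit <- keys0 %in% names(tree_splits(rep_tree))
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (skipped > 0.1 * n_reps) {
    stop(sprintf("%d of %d bootstrap replicates degenerate", skipped, n_reps),
         call. = FALSE)
  }
  eff <- n_reps - skipped
  support <- round(100 * counts / eff)

  pp <- ape::prop.part(tree0)
  labels <- attr(pp, "labels")
  nt <- length(labels)
  node_label <- character(length(pp))
  for (k in seq_along(pp)) {
    if (nt + k == nt + 1L) { node_label[k] <- ""; next }
    clade <- labels[pp[[k]]]
    key <- split_key(clade, labels)
    node_label[k] <- as.character(support[[key]])
  }
  tree0$node.label <- node_label
  attr(tree0, "n_effective") <- eff
  tree0
}

#' Write a tree to a Newick file
#'
#' Supports are carried as internal node labels (the value after the
#' closing parenthesis).
#'
#' @param tree `phylo` object.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return `phylo` object; node labels (supports) preserved.
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
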