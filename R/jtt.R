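# The Jones-Taylor-Thornton (JTT) empirical amino-acid substitution model:
# data loading, transition probabilities, pairwise maximum-likelihood
# distances, and sequence-pair simulation used by the test oracles.

# Checksums of the packaged model data; asserted at load so a silently
# corrupted data file cannot produce plausible-looking distances.
.JTT_MD5 <- c(
  jtt_exchangeabilities.tsv = "70810e2f4a85dd9362375eaaf28cabea",
  jtt_frequencies.tsv       = "a663b628afe59f34ca0e57e899bc4db4"
)

.jtt_cache <- new.env(parent = emptyenv())

#' Load the JTT substitution model
#'
#' Reads the packaged exchangeability matrix and equilibrium frequencies of
#' the Jones-Taylor-Thornton model, builds the instantaneous rate matrix Q
#' normalised to one expected substitution per site per unit time, and
#' caches its spectral decomposition for fast transition-probability
#' evaluation. File checksums are verified on first load.
#'
#' @return A list with components `S` (symmetric exchangeabilities), `pi`
#'   (equilibrium frequencies, PAML residue order), `Q` (normalised rate
#'   matrix) and the cached eigendecomposition used by [jtt_prob()].
#' @export
#' @examples
#' m <- jtt_model()
#' sum(m$pi)               # 1
#' max(abs(rowSums(m$Q)))  # ~0
jtt_model <- function() {
  if (!is.null(.jtt_cache$model)) {
    return(.jtt_cache$model)
  }
  exch_file <- system.file("extdata", "jtt_exchangeabilities.tsv",
                           package = "mipclass", mustWork = TRUE)
  freq_file <- system.file("extdata", "jtt_frequencies.tsv",
                           package = "mipclass", mustWork = TRUE)
  sums <- tools::md5sum(c(exch_file, freq_file))
  expected <- .JTT_MD5[basename(names(sums))]
  if (!all(unname(sums) == unname(expected))) {
    stop("JTT model data files failed checksum verification", call. = FALSE)
  }

  exch <- utils::read.delim(exch_file, stringsAsFactors = FALSE)
  S <- as.matrix(exch[, -1])
  rownames(S) <- exch$aa
  colnames(S) <- colnames(exch)[-1]
  S <- S[AA20, AA20]
  freq <- utils::read.delim(freq_file, stringsAsFactors = FALSE)
  pi <- stats::setNames(freq$freq, freq$aa)[AA20]
  pi <- pi / sum(pi)

  stopifnot(isTRUE(all.equal(S, t(S))), all(diag(S) == 0), all(pi > 0))

  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  # scale to 1 expected substitution per site per unit branch length
  Q <- Q / sum(pi * -diag(Q))
  dimnames(Q) <- list(AA20, AA20)

  # reversible Q: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric, so a real
  # spectral decomposition exists and exp(Qd) is cheap for any d
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  left  <- diag(1 / sp) %*% eg$vectors    # 20 x 20
  right <- t(eg$vectors) %*% diag(sp)

  model <- list(S = S, pi = pi, Q = Q,
                eigenvalues = eg$values, left = left, right = right)
  .jtt_cache$model <- model
  model
}

#' JTT transition-probability matrix
#'
#' @param d branch length (expected substitutions per site), `d >= 0`.
#' @param model result of [jtt_model()]; loaded automatically if missing.
#' @return The 20 x 20 stochastic matrix `P(d) = exp(Q d)` with rows the
#'   ancestral residue and columns the descendant residue, PAML order.
#' @export
jtt_prob <- function(d, model = jtt_model()) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, is.finite(d))
  P <- model$left %*% (exp(model$eigenvalues * d) * model$right)
  # numerical cleanup: tiny negatives from the eigendecomposition
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

# 20 x 20 table of paired residue counts over pairwise-deletion columns
# (columns ungapped in both rows).
pair_count_table <- function(row_a, row_b) {
  a <- seq_chars(row_a)
  b <- seq_chars(row_b)
  if (length(a) != length(b)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  ia <- match(a, AA20)
  ib <- match(b, AA20)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) {
    stop("no shared ungapped columns between the two rows", call. = FALSE)
  }
  idx <- (ia[keep] - 1L) * 20L + ib[keep]
  matrix(tabulate(idx, nbins = 400L), nrow = 20L, byrow = TRUE,
         dimnames = list(AA20, AA20))
}

# log-likelihood of a paired count table at distance d
jtt_loglik <- function(d, counts, model) {
  P <- model$left %*% (exp(model$eigenvalues * d) * model$right)
  M <- model$pi * P            # pi_a * P_ab, recycled down rows
  M[M < 1e-300] <- 1e-300
  sum(counts * log(M))
}

#' Pairwise maximum-likelihood distance under the JTT model
#'
#' Estimates the evolutionary distance between two aligned protein
#' sequences as the `d` maximising the likelihood
#' `prod over sites pi(a) P(a -> b | d)` with `P` from the JTT rate matrix.
#' Columns gapped in either row are dropped (pairwise deletion). The
#' likelihood is unimodal in `d`; it is maximised by bracketed 1-D search
#' on `[0, d_max]` to the stated tolerance.
#'
#' @param row_a,row_b equal-length (optionally gapped) residue strings.
#' @param d_max saturation cap in substitutions per site (default 10).
#' @param tol optimisation tolerance (default 1e-6).
#' @return The distance estimate. Identical rows give exactly 0. When the
#'   optimiser hits `d_max` the value carries `attr(, "saturated") = TRUE`.
#' @export
#' @examples
#' jtt_distance("ARNDCQEGHILK", "ARNDCQEGHILK")  # 0
jtt_distance <- function(row_a, row_b, d_max = 10, tol = 1e-6) {
  model <- jtt_model()
  counts <- pair_count_table(row_a, row_b)
  if (sum(counts) == sum(diag(counts))) {
    return(0)
  }
  opt <- stats::optimize(jtt_loglik, interval = c(0, d_max),
                         counts = counts, model = model,
                         maximum = TRUE, tol = tol)
  d <- opt$maximum
  # optimize() never returns the exact endpoints; snap when at the brackets
  if (d > d_max - 2 * tol) {
    d <- d_max
    attr(d, "saturated") <- TRUE
  }
  d
}

#' JTT distance matrix from a multiple alignment
#'
#' @param msa named character vector of equal-length gapped rows.
#' @inheritParams jtt_distance
#' @return Symmetric matrix of pairwise ML distances with zero diagonal,
#'   row and column names taken from `msa`.
#' @export
jtt_dist_matrix <- function(msa, d_max = 10, tol = 1e-6) {
  msa <- as_msa(msa)
  n <- length(msa)
  ids <- names(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- jtt_distance(msa[[i]], msa[[j]], d_max = d_max, tol = tol)
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  D
}

#' Simulate an aligned sequence pair under the JTT model
#'
#' Draws an ancestral sequence from the JTT equilibrium frequencies and
#' evolves one copy for branch length `d`; used to check distance
#' estimation against known truth.
#'
#' @param d true distance (substitutions per site).
#' @param n_sites number of alignment columns.
#' @param seed RNG seed.
#' @return Character vector of two equal-length ungapped rows named
#'   `"anc"` and `"des"`.
#' @export
simulate_jtt_pair <- function(d, n_sites, seed) {
  model <- jtt_model()
  P <- jtt_prob(d, model)
  with_seed(seed, {
    anc <- sample(AA20, n_sites, replace = TRUE, prob = model$pi)
    des <- vapply(anc, function(a) {
      sample(AA20, 1L, prob = P[a, ])
    }, character(1), USE.NAMES = FALSE)
    c(anc = chars_seq(anc), des = chars_seq(des))
  })
}
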