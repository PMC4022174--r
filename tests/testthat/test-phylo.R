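test_that("terminal trimming removes ragged overhangs and is idempotent", {
  msa <- c(a = "--ACD-EF--",
           b = "G-ACDCEFK-",
           c = "--ACDCEF--")
  tr <- trim_msa(msa, terminal_gap_fraction = 0.5)
  expect_identical(unclass(tr)[["a"]], "ACD-EF")
  expect_identical(unclass(tr)[["b"]], "ACDCEF")  # interior column kept
  expect_identical(unclass(trim_msa(tr, 0.5)), unclass(tr))
  expect_error(trim_msa(c(a = "---", b = "A--"), 0.4), "every column")
})

test_that("the JTT model is a proper reversible Markov generator", {
  m <- jtt_model()
  expect_equal(sum(m$pi), 1)
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_equal(sum(m$pi * -diag(m$Q)), 1)   # 1 substitution/site/unit time
  flux <- m$pi * m$Q                         # detailed balance pi_i q_ij
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  expect_equal(jtt_prob(0), diag(20), ignore_attr = TRUE)
  P <- jtt_prob(0.4)
  expect_equal(unname(rowSums(P)), rep(1, 20))
  expect_true(all(P >= 0))
  # Chapman-Kolmogorov: P(a) P(b) = P(a + b)
  expect_equal(jtt_prob(0.15) %*% jtt_prob(0.25), jtt_prob(0.4),
               tolerance = 1e-10)
})

test_that("transition probabilities agree with a direct matrix exponential", {
  skip_if_not_installed("Matrix")
  m <- jtt_model()
  P_direct <- as.matrix(Matrix::expm(Matrix::Matrix(m$Q * 0.37)))
  expect_equal(unname(jtt_prob(0.37)), unname(P_direct), tolerance = 1e-8)
})

test_that("identical sequences are at distance exactly zero and distances are symmetric", {
  s <- "ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV"
  expect_identical(jtt_distance(s, s), 0)
  pair <- simulate_jtt_pair(0.3, 400, seed = 5)
  expect_equal(jtt_distance(pair["anc"], pair["des"]),
               jtt_distance(pair["des"], pair["anc"]))
})

test_that("maximum-likelihood distances recover simulated branch lengths", {
  for (d in c(0.05, 0.2, 0.5)) {
    pair <- simulate_jtt_pair(d, 10000, seed = round(1000 * d))
    est <- jtt_distance(pair["anc"], pair["des"])
    expect_lt(abs(est - d), 0.05 * d + 0.01)
  }
})

test_that("the likelihood search finds the grid-search optimum", {
  pair <- simulate_jtt_pair(0.25, 2000, seed = 9)
  counts <- mipclass:::pair_count_table(pair["anc"], pair["des"])
  model <- jtt_model()
  est <- jtt_distance(pair["anc"], pair["des"])
  grid <- seq(0.01, 1.5, by = 0.001)
  ll <- vapply(grid, mipclass:::jtt_loglik, numeric(1),
               counts = counts, model = model)
  expect_lt(abs(est - grid[which.max(ll)]), 2e-3)
  expect_gte(mipclass:::jtt_loglik(est, counts, model), max(ll) - 1e-6)
})

test_that("saturated pairs are capped at the distance ceiling and flagged", {
  pair <- simulate_jtt_pair(0.8, 500, seed = 12)
  est <- jtt_distance(pair["anc"], pair["des"], d_max = 0.3)
  expect_equal(as.numeric(est), 0.3)
  expect_true(isTRUE(attr(est, "saturated")))
})

test_that("gapped columns are dropped pairwise before distance estimation", {
  pair <- simulate_jtt_pair(0.2, 300, seed = 31)
  a <- pair["anc"]; b <- pair["des"]
  ga <- paste0("----", a)
  gb <- paste0("WYWY", b)
  expect_equal(jtt_distance(ga, gb), jtt_distance(a, b))
  expect_error(jtt_distance("----", "AAAA"), "ungapped")
})

test_that("neighbour joining reproduces the classic four-taxon worked example", {
  D <- matrix(c(0, 3, 7, 8,
                3, 0, 8, 9,
                7, 8, 0, 5,
                8, 9, 5, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_identical(ape::Ntip(tr), 4L)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4],
                                                    LETTERS[1:4]], D)
})

test_that("three taxa give the closed-form star tree", {
  D <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(D)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("x", "y", "z")]), c(0, 2, 3))
})

test_that("additive distance matrices are recovered exactly", {
  for (k in 1:10) {
    sim <- oracle_additive_matrix(n_taxa = 4 + (k %% 9), seed = 5000 + k)
    tr <- nj_tree(sim$D)
    expect_identical(oracle_rf(tr, sim$tree), 0)
    C <- as.matrix(ape::cophenetic.phylo(tr))[rownames(sim$D), rownames(sim$D)]
    expect_lt(max(abs(C - sim$D)), 1e-8)
  }
})

test_that("tree topology matches the reference NJ implementation on noisy input", {
  for (k in 1:5) {
    sim <- oracle_additive_matrix(n_taxa = 8, seed = 7000 + k)
    set.seed(k)
    noise <- matrix(stats::runif(64, 0, 0.02), 8, 8)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    D <- sim$D + noise
    expect_identical(oracle_rf(nj_tree(D), ape::nj(as.dist(D))), 0)
  }
})

test_that("distance estimates agree with an independent JTT implementation", {
  skip_if_not_installed("phangorn")
  fam <- generate_family(mip_scaffold_template(), n = 6, divergence = 0.2,
                         indel_rate = 0, seed = 61)
  msa <- as_msa(fam$sequences)
  D <- jtt_dist_matrix(msa)
  pd <- phangorn::as.phyDat(do.call(rbind, strsplit(unclass(msa), "")),
                            type = "AA")
  D_ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  expect_equal(D, D_ref[rownames(D), colnames(D)], tolerance = 2e-3)
})

test_that("invalid distance matrices are rejected with clear messages", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  M <- matrix(0, 3, 3)
  expect_error(nj_tree(M), "names")
  M2 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(M2), "symmetric")
})

test_that("monophyly queries read the defining bipartition and its support", {
  tr <- ape::read.tree(text = "(((a:1,b:1)90:1,c:1)75:1,(d:1,e:1)88:1,f:1);")
  res <- is_monophyletic(tr, c("a", "b"))
  expect_true(res$monophyletic)
  expect_equal(res$support, 90)
  res2 <- is_monophyletic(tr, c("d", "e"))
  expect_true(res2$monophyletic)
  expect_equal(res2$support, 88)
  expect_false(is_monophyletic(tr, c("a", "c"))$monophyletic)
  expect_false(is_monophyletic(tr, c("b", "d"))$monophyletic)
  expect_true(is_monophyletic(tr, c("a", "b", "c"))$monophyletic)
  expect_error(is_monophyletic(tr, c("a", "zz")), "unknown")
  expect_error(is_monophyletic(tr, "a"), "at least 2")
  # complement of one tip is always separated by that tip's pendant edge
  expect_true(is_monophyletic(tr, letters[1:5])$monophyletic)
})

test_that("bootstrap supports are reproducible and pick out planted families", {
  fams <- lapply(c("PIP", "GIP", "LIP", "MIPC"), function(sf) {
    generate_family(mipclass:::subfamily_template(sf), n = 4,
                    divergence = 0.05, indel_rate = 0,
                    seed = 900 + match(sf, c("PIP", "GIP", "LIP", "MIPC")))
  })
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  msa <- build_true_msa(truth)
  t1 <- bootstrap_supports(msa, n_reps = 40, seed = 17)
  t2 <- bootstrap_supports(msa, n_reps = 40, seed = 17)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  for (sf in c("PIP", "GIP", "LIP", "MIPC")) {
    members <- truth$seq_id[truth$subfamily == sf]
    res <- is_monophyletic(t1, members)
    expect_true(res$monophyletic)
    expect_equal(res$support, 100)
  }
  expect_equal(attr(t1, "n_effective"), 40)
})

test_that("trees round-trip through Newick files with supports and lengths", {
  sim <- oracle_additive_matrix(n_taxa = 7, seed = 321)
  tr <- nj_tree(sim$D)
  tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
  path <- file.path(tempdir(), "rt.nwk")
  write_tree_newick(tr, path)
  back <- read_tree_newick(path)
  expect_identical(oracle_rf(tr, back), 0)
  expect_identical(back$node.label[order(back$node.label)],
                   tr$node.label[order(tr$node.label)])
  co <- as.matrix(ape::cophenetic.phylo(back))
  expect_lt(max(abs(co[rownames(sim$D), rownames(sim$D)] -
                      as.matrix(ape::cophenetic.phylo(tr))[rownames(sim$D),
                                                           rownames(sim$D)])),
            1e-6)
  unlink(path)
})
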