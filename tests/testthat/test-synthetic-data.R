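test_that("zero divergence with the default indel rate reproduces the template exactly", {
  tpl <- mip_scaffold_template()
  fam <- generate_family(tpl, n = 5, divergence = 0, seed = 11)
  expect_true(all(fam$sequences == tpl$residues))
  expect_false(any(grepl("-", fam$truth$aln_seq, fixed = TRUE)))
  expect_false(any(grepl("-", fam$truth$aln_ref, fixed = TRUE)))
  expect_equal(fam$truth$length, rep(300L, 5))
})

test_that("uniform substitution produces the 20-state Jukes-Cantor difference fraction", {
  tpl <- mip_scaffold_template()
  d <- 0.3
  fam <- generate_family(tpl, n = 40, divergence = d, indel_rate = 0,
                         seed = 202)
  prot <- mipclass:::template_protected_positions(tpl)
  evolvable <- setdiff(seq_len(300), c(prot, tpl$conserved))
  tch <- strsplit(tpl$residues, "")[[1]]
  diffs <- vapply(fam$sequences, function(s) {
    sum(strsplit(s, "")[[1]][evolvable] != tch[evolvable])
  }, numeric(1))
  p_obs <- sum(diffs) / (40 * length(evolvable))
  p_exp <- (19 / 20) * (1 - exp(-20 * d / 19))
  se <- sqrt(p_exp * (1 - p_exp) / (40 * length(evolvable)))
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("planted boxes, filter, C-terminus and conserved cores never mutate", {
  tpl <- mip_scaffold_template()
  fam <- generate_family(tpl, n = 20, divergence = 0.6, indel_rate = 0,
                         seed = 33)
  tch <- strsplit(tpl$residues, "")[[1]]
  fixed <- sort(unique(c(mipclass:::template_protected_positions(tpl),
                         tpl$conserved)))
  for (s in fam$sequences) {
    expect_identical(strsplit(s, "")[[1]][fixed], tch[fixed])
  }
})

test_that("indels never destroy planted features and truth coordinates track them", {
  fam <- generate_family(mip_scaffold_template(), n = 30, divergence = 0.25,
                         indel_rate = 0.01, seed = 404)
  tr <- fam$truth
  for (k in seq_len(nrow(tr))) {
    s <- fam$sequences[[tr$seq_id[k]]]
    expect_identical(substr(s, tr$box1_start[k], tr$box1_start[k] + 2),
                     tr$planted_box1[k])
    expect_identical(substr(s, tr$box2_start[k], tr$box2_start[k] + 2),
                     tr$planted_box2[k])
    got <- substring(s, c(tr$h2_pos[k], tr$h5_pos[k], tr$le1_pos[k],
                          tr$le2_pos[k]),
                     c(tr$h2_pos[k], tr$h5_pos[k], tr$le1_pos[k],
                       tr$le2_pos[k]))
    expect_identical(paste(got, collapse = ""), tr$planted_filter[k])
    expect_identical(substr(s, nchar(s), nchar(s)), tr$planted_cterm[k])
    expect_identical(nchar(s), tr$length[k])
  }
})

test_that("truth alignment rows degap to the sequence and the template", {
  tpl <- mip_scaffold_template()
  fam <- generate_family(tpl, n = 15, divergence = 0.3, seed = 55)
  for (k in seq_len(nrow(fam$truth))) {
    expect_identical(gsub("-", "", fam$truth$aln_seq[k], fixed = TRUE),
                     unname(fam$sequences[[fam$truth$seq_id[k]]]))
    expect_identical(gsub("-", "", fam$truth$aln_ref[k], fixed = TRUE),
                     tpl$residues)
    expect_identical(nchar(fam$truth$aln_seq[k]), nchar(fam$truth$aln_ref[k]))
  }
})

test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  tpl <- mip_scaffold_template()
  a <- generate_family(tpl, n = 6, divergence = 0.2, seed = 99)
  b <- generate_family(tpl, n = 6, divergence = 0.2, seed = 99)
  c <- generate_family(tpl, n = 6, divergence = 0.2, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$sequences, c$sequences))

  p1 <- generate_heterokont_panel(seed = 7)
  p2 <- generate_heterokont_panel(seed = 7)
  p3 <- generate_heterokont_panel(seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequences, p3$sequences))
})

test_that("generator rejects invalid divergence, counts and rates", {
  tpl <- mip_scaffold_template()
  expect_error(generate_family(tpl, n = 0, divergence = 0.1, seed = 1))
  expect_error(generate_family(tpl, n = 2, divergence = 1, seed = 1))
  expect_error(generate_family(tpl, n = 2, divergence = -0.1, seed = 1))
  expect_error(generate_family(tpl, n = 2, divergence = 0.1,
                               indel_rate = -1, seed = 1))
})

test_that("template constructor enforces the MIP feature geometry", {
  bg <- paste(rep("ARNDCQEGHILKMFPSTWYV", 15), collapse = "")
  expect_s3_class(mip_template("t", bg, 78, 185, 60, 175, 188, 190),
                  "mip_template")
  expect_error(mip_template("t", bg, 185, 78, 60, 175, 188, 190))
  expect_error(mip_template("t", bg, 78, 185, 60, 175, 195, 196))
  expect_error(mip_template("t", substr(bg, 1, 150), 78, 100, 60, 90,
                            103, 105))
  expect_error(mip_template("t", bg, 78, 185, 60, 175, 188, 190,
                            conserved = 0:5))
})

test_that("the heterokont panel carries the published filter strings and motif variants", {
  panel <- generate_heterokont_panel(seed = 1)
  tr <- panel$truth
  expect_identical(sort(names(panel$sequences)), sort(tr$seq_id))
  expect_length(panel$sequences, 20L)

  want <- c(TpMIP1 = "IAGV", TpMIP2 = "WIPL", ToMIP1 = "WLPL",
            ToMIP2 = "IAGV", PtMIP1 = "WVAR", PtMIP2 = "WVGR",
            PtMIP3 = "WVAR", PtMIP4 = "FHCR", PtMIP5 = "WLPL",
            NgMIP = "WLPI", SarMIP = "WLPL", PnmMIP = "WLPL",
            FcMIP = "WLPL", EsAQP = "FHAR", EsPIP = "FHCR",
            EsMIP = "WLPI", AaMIP1 = "YVPL", AaMIP2 = "FICR",
            AaMIP3 = "TASV", AaMIP4 = "FHCR")
  got <- stats::setNames(tr$planted_filter, tr$seq_id)
  expect_identical(got[names(want)], want)

  npm <- sort(tr$seq_id[tr$planted_box2 == "NPM"])
  expect_identical(npm, sort(c("EsMIP", "NgMIP", "PtMIP5", "PnmMIP",
                               "FcMIP", "SarMIP", "TpMIP2", "ToMIP1")))
  expect_identical(tr$planted_box1[tr$seq_id == "AaMIP4"], "NGA")
  expect_identical(tr$planted_box1[tr$seq_id == "PtMIP4"], "NPG")
  expect_identical(sort(tr$seq_id[tr$planted_cterm == "K"]), npm)
})

test_that("the panel length classes match the published size ranges", {
  panel <- generate_heterokont_panel(seed = 42)
  tr <- panel$truth
  len <- stats::setNames(tr$length, tr$seq_id)
  expect_identical(unname(len["EsMIP"]), 225L)
  expect_identical(unname(len["NgMIP"]), 230L)
  other_lip <- setdiff(tr$seq_id[tr$subfamily == "LIP"],
                       c("EsMIP", "NgMIP"))
  expect_true(all(len[other_lip] >= 280 & len[other_lip] <= 317))
  expect_identical(unname(len), unname(nchar(panel$sequences[tr$seq_id])))
})

test_that("simulated sets round-trip losslessly through the truth tables on disk", {
  fam <- generate_family(mip_scaffold_template(), n = 4, divergence = 0.15,
                         seed = 5)
  dir <- file.path(tempdir(), "truth_rt")
  write_truth_tables(fam, dir)
  back <- read_truth_tables(dir)
  expect_identical(back$sequences, fam$sequences)
  expect_identical(back$truth, fam$truth)
  unlink(dir, recursive = TRUE)
})
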