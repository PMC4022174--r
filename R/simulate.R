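# Simulator for MIP-like protein sequences with planted, fully recorded
# truth: NPA-like boxes on loops B and E, the four ar/R filter residues,
# the C-terminal residue, subfamily-structured divergence, and exact true
# alignments back to the generating template.

# Internal seed anchoring the canonical scaffold and the packaged panel
# backgrounds; member-level variation comes from the caller's seed.
.SCAFFOLD_SEED <- 104729L
.SCAFFOLD_LEN <- 300L

#' Construct a MIP template
#'
#' A template is a residue string plus the coordinates of its planted
#' features: the two NPA-like boxes (loop B, loop E), the four ar/R
#' selectivity-filter residues (roles H2, H5, LE1, LE2) and a subfamily
#' label. All coordinates are 1-based and inclusive.
#'
#' @param template_id short identifier.
#' @param residues string over the 20 standard amino-acid letters,
#'   length 200 to 350.
#' @param box1_start,box2_start start positions of the two 3-residue boxes;
#'   `box1_start < box2_start`.
#' @param h2_pos,h5_pos,le1_pos,le2_pos filter residue positions; LE1 and
#'   LE2 must lie within 6 residues downstream of `box2_start`.
#' @param subfamily_label one of PIP, GIP, MIPE, LIP, SIP, MIPC,
#'   bacterial, unclassified.
#' @param conserved integer positions of family-identity core columns
#'   (transmembrane stretches) that [generate_family()] holds fixed:
#'   neither substitutions nor indels touch them. Empty by default.
#' @return An object of class `mip_template`.
#' @export
mip_template <- function(template_id, residues, box1_start, box2_start,
                         h2_pos, h5_pos, le1_pos, le2_pos,
                         subfamily_label = "unclassified",
                         conserved = integer(0)) {
  assert_standard_aa(residues, what = "template residues")
  L <- nchar(residues)
  if (L < 200 || L > 350) {
    stop("template length must lie in [200, 350]", call. = FALSE)
  }
  subfamily_label <- match.arg(
    subfamily_label,
    c("PIP", "GIP", "MIPE", "LIP", "SIP", "MIPC", "bacterial", "unclassified"))
  pos <- c(box1 = box1_start, box2 = box2_start, h2 = h2_pos,
           h5 = h5_pos, le1 = le1_pos, le2 = le2_pos)
  if (any(pos < 1) || box1_start + 2 > L || box2_start + 2 > L ||
      any(c(h2_pos, h5_pos, le1_pos, le2_pos) > L)) {
    stop("planted positions fall outside the sequence", call. = FALSE)
  }
  if (box1_start >= box2_start) {
    stop("box1_start must precede box2_start", call. = FALSE)
  }
  if (le1_pos <= box2_start || le1_pos > box2_start + 6 ||
      le2_pos <= box2_start || le2_pos > box2_start + 6 || le1_pos >= le2_pos) {
    stop("LE1 and LE2 must lie within 6 residues downstream of box2_start",
         call. = FALSE)
  }
  conserved <- as.integer(conserved)
  if (length(conserved) && (any(conserved < 1) || any(conserved > L))) {
    stop("conserved positions fall outside the sequence", call. = FALSE)
  }
  structure(list(template_id = template_id, residues = residues,
                 box1_start = box1_start, box2_start = box2_start,
                 h2_pos = h2_pos, h5_pos = h5_pos,
                 le1_pos = le1_pos, le2_pos = le2_pos,
                 subfamily_label = subfamily_label,
                 conserved = conserved),
            class = "mip_template")
}

#' @export
print.mip_template <- function(x, ...) {
  cat(sprintf("MIP template '%s' (%s), %d aa; boxes %d/%d, filter %d/%d/%d/%d\n",
              x$template_id, x$subfamily_label, nchar(x$residues),
              x$box1_start, x$box2_start,
              x$h2_pos, x$h5_pos, x$le1_pos, x$le2_pos))
  invisible(x)
}

# Exact planted positions (substitutions are never applied here).
template_protected_positions <- function(tpl, L = nchar(tpl$residues)) {
  unique(c(tpl$box1_start:(tpl$box1_start + 2L),
           tpl$box2_start:(tpl$box2_start + 2L),
           tpl$h2_pos, tpl$h5_pos, tpl$le1_pos, tpl$le2_pos, L))
}

# Scaffold columns held invariant across subfamilies, panel members and
# the packaged references: the transmembrane cores flanking H2, H5 and
# the two boxes plus the loop-E region. Real MIP families keep exactly
# these stretches recognisably conserved while loops drift freely.
conserved_columns <- function() {
  c(55:65, 72:86, 100:110, 140:150, 170:177, 182:196)
}

# Windows indels must not touch: box start-1..start+3, filter +-1, the
# C-terminal pair.
template_indel_windows <- function(tpl, L = nchar(tpl$residues)) {
  w <- c((tpl$box1_start - 1L):(tpl$box1_start + 3L),
         (tpl$box2_start - 1L):(tpl$box2_start + 3L),
         (tpl$h2_pos - 1L):(tpl$h2_pos + 1L),
         (tpl$h5_pos - 1L):(tpl$h5_pos + 1L),
         (tpl$le1_pos - 1L):(tpl$le1_pos + 1L),
         (tpl$le2_pos - 1L):(tpl$le2_pos + 1L),
         (L - 1L):L)
  unique(w[w >= 1L & w <= L])
}

# Rewrite chance occurrences of N-[PG] outside the planted boxes so planted
# motifs are the only scanner candidates in generated sequences. Positions
# in `protect` are never modified; matches already present in `template`
# (user-supplied templates) are left alone. Consumes RNG.
suppress_decoys <- function(chars, protect, template = NULL) {
  freqs <- jtt_model()$pi
  repeat {
    n <- length(chars)
    hit <- which(chars[-n] == "N" & chars[-1] %in% c("P", "G"))
    hit <- hit[!(hit %in% protect)]            # planted box starts
    if (!is.null(template)) {
      same <- hit[template[hit] == "N" & template[hit + 1L] == chars[hit + 1L]]
      hit <- setdiff(hit, same)
    }
    if (!length(hit)) break
    i <- hit[1]
    if (!((i + 1L) %in% protect)) {
      pool <- setdiff(AA20, c("P", "G", "N"))
      chars[i + 1L] <- sample(pool, 1L, prob = freqs[pool])
    } else {
      pool <- setdiff(AA20, "N")
      chars[i] <- sample(pool, 1L, prob = freqs[pool])
    }
  }
  chars
}

# Background residues from the fixed JTT equilibrium frequency table.
draw_background <- function(n) {
  sample(AA20, n, replace = TRUE, prob = jtt_model()$pi)
}

# Poisson-hit chain of uniform replacements; expected hits per site = d.
mutate_uniform <- function(chars, sites, d) {
  hits <- stats::rpois(length(sites), d)
  for (k in which(hits > 0L)) {
    p <- sites[k]
    for (h in seq_len(hits[k])) {
      chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
    }
  }
  chars
}

scaffold_cache <- new.env(parent = emptyenv())

#' The canonical MIP scaffold template
#'
#' A fixed 300-residue template anchoring one shared coordinate system for
#' the packaged reference annotations, the heterokont panel and any
#' simulated family that wants cross-alignable sequences. The background
#' is drawn once from the JTT equilibrium frequencies under an internal
#' seed; planted features are a canonical aquaporin layout (NPA boxes at
#' 78 and 185, filter F60/H175/A188/R190).
#'
#' @return An `mip_template`.
#' @export
mip_scaffold_template <- function() {
  if (!is.null(scaffold_cache$tpl)) return(scaffold_cache$tpl)
  tpl <- with_seed(.SCAFFOLD_SEED, {
    chars <- draw_background(.SCAFFOLD_LEN)
    chars <- plant_features(chars, box1_start = 78L, box2_start = 185L,
                            box1 = "NPA", box2 = "NPA",
                            h2_pos = 60L, h5_pos = 175L,
                            le1_pos = 188L, le2_pos = 190L,
                            filter = "FHAR", cterm = "S")
    chars <- suppress_decoys(chars, protect = c(78L, 185L))
    mip_template("MIP_scaffold", chars_seq(chars),
                 box1_start = 78L, box2_start = 185L,
                 h2_pos = 60L, h5_pos = 175L, le1_pos = 188L, le2_pos = 190L,
                 subfamily_label = "unclassified",
                 conserved = conserved_columns())
  })
  scaffold_cache$tpl <- tpl
  tpl
}

plant_features <- function(chars, box1_start, box2_start, box1, box2,
                           h2_pos, h5_pos, le1_pos, le2_pos, filter, cterm) {
  b1 <- seq_chars(box1); b2 <- seq_chars(box2); fl <- seq_chars(filter)
  chars[box1_start:(box1_start + 2L)] <- b1
  chars[box2_start:(box2_start + 2L)] <- b2
  chars[c(h2_pos, h5_pos, le1_pos, le2_pos)] <- fl
  chars[length(chars)] <- cterm
  chars
}

# Subfamily ancestors: the scaffold diverged by 0.5 expected
# substitutions/site at unprotected sites, one fixed stream per subfamily.
subfamily_template <- function(subfamily) {
  key <- paste0("sub_", subfamily)
  if (!is.null(scaffold_cache[[key]])) return(scaffold_cache[[key]])
  base <- mip_scaffold_template()
  idx <- match(subfamily,
               c("PIP", "GIP", "MIPE", "LIP", "SIP", "MIPC",
                 "bacterial", "unclassified"))
  stopifnot(!is.na(idx))
  tpl <- with_seed(.SCAFFOLD_SEED + idx, {
    chars <- seq_chars(base$residues)
    prot <- template_protected_positions(base)
    sites <- setdiff(seq_along(chars), c(prot, conserved_columns()))
    chars <- mutate_uniform(chars, sites, 0.5)
    chars <- suppress_decoys(chars, protect = c(base$box1_start, base$box2_start),
                             template = seq_chars(base$residues))
    tpl <- base
    tpl$template_id <- paste0("MIP_", subfamily)
    tpl$residues <- chars_seq(chars)
    tpl$subfamily_label <- subfamily
    class(tpl) <- "mip_template"
    tpl
  })
  scaffold_cache[[key]] <- tpl
  tpl
}

#' Simulate a family of MIP-like sequences from a template
#'
#' Each output derives from the template by per-site point substitutions
#' and optional indels; the planted boxes, filter residues and C-terminal
#' residue are protected from mutation, and chance creation of decoy
#' N-\[PG\] motifs in the background is suppressed so the planted boxes
#' remain the only motif candidates. Templates carrying a `conserved`
#' core set (the packaged scaffold and its subfamily derivatives do)
#' additionally keep those columns free of substitutions and indels, so
#' `divergence` is the expected substitution load on the evolvable
#' (loop/terminal) sites only — mirroring how real MIP divergence
#' concentrates outside the transmembrane cores. Truth rows record the planted values,
#' their coordinates in the mutated sequence and an exact pairwise
#' alignment back to the template.
#'
#' Substitution processes: `"uniform"` draws a Poisson(divergence) number
#' of hits per site, each replacing the residue uniformly among the 19
#' alternatives (the 20-state Jukes-Cantor-type process, observed
#' difference probability `(19/20) (1 - exp(-20 d / 19))`);
#' `"jtt"` samples the descendant residue from the JTT transition matrix
#' at distance `divergence`.
#'
#' Indels: event count Poisson(`indel_rate * length`), deletion or
#' insertion with equal probability, lengths `1 + Geometric(1/2)` (mean
#' 2); events falling on a protected window (box start-1..start+3, filter
#' positions +-1, the terminal pair) are re-drawn. When `indel_rate` is
#' `NULL` it defaults to `divergence / 60`, so zero divergence is exactly
#' the identity.
#'
#' @param template an [mip_template()].
#' @param n number of sequences (>= 1).
#' @param divergence expected substitutions per site, in `[0, 1)`.
#' @param indel_rate per-site indel event probability, or `NULL` for the
#'   divergence-coupled default.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param model `"uniform"` or `"jtt"`.
#' @return `list(sequences = named character, truth = data.frame)`.
#' @export
#' @examples
#' fam <- generate_family(mip_scaffold_template(), n = 2,
#'                        divergence = 0.2, seed = 1)
#' fam$truth$planted_filter
generate_family <- function(template, n, divergence, indel_rate = NULL,
                            seed, model = c("uniform", "jtt")) {
  stopifnot(inherits(template, "mip_template"))
  model <- match.arg(model)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1) {
    stop("'divergence' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(indel_rate) && (!is.numeric(indel_rate) || indel_rate < 0)) {
    stop("'indel_rate' must be non-negative", call. = FALSE)
  }
  rate <- indel_rate %||% (divergence / 60)

  tchars <- seq_chars(template$residues)
  L <- length(tchars)
  prot <- template_protected_positions(template, L)
  core <- template$conserved %||% integer(0)
  excl <- unique(c(template_indel_windows(template, L), core))
  sites <- setdiff(seq_len(L), c(prot, core))
  P_jtt <- if (model == "jtt") jtt_prob(divergence) else NULL

  seqs <- character(n)
  truths <- vector("list", n)
  with_seed(seed, {
    for (k in seq_len(n)) {
      chars <- tchars
      if (divergence > 0) {
        if (model == "uniform") {
          chars <- mutate_uniform(chars, sites, divergence)
        } else {
          chars[sites] <- vapply(chars[sites], function(a) {
            sample(AA20, 1L, prob = P_jtt[a, ])
          }, character(1), USE.NAMES = FALSE)
        }
        chars <- suppress_decoys(
          chars, protect = c(template$box1_start, template$box2_start),
          template = tchars)
      }

      present <- rep(TRUE, L)
      ins <- vector("list", L)
      n_ev <- stats::rpois(1L, rate * L)
      for (ev in seq_len(n_ev)) {
        is_del <- stats::runif(1) < 0.5
        len <- 1L + stats::rgeom(1L, 0.5)
        for (try in 1:50) {
          if (is_del) {
            start <- sample.int(L - len + 1L, 1L)
            win <- start:(start + len - 1L)
            if (all(present[win]) && !any(win %in% excl)) {
              present[win] <- FALSE
              break
            }
          } else {
            p <- sample.int(L - 2L, 1L)
            if (present[p] && !(p %in% excl)) {
              ins[[p]] <- c(ins[[p]], draw_background(len))
              break
            }
          }
        }
      }

      # assemble with origin bookkeeping so decoy suppression at deletion
      # junctions can be written back
      out_chars <- character(0)
      out_tpos <- integer(0)   # template position, 0 for insertions
      for (p in seq_len(L)) {
        if (present[p]) {
          out_chars <- c(out_chars, chars[p])
          out_tpos <- c(out_tpos, p)
        }
        if (!is.null(ins[[p]])) {
          out_chars <- c(out_chars, ins[[p]])
          out_tpos <- c(out_tpos, rep(0L, length(ins[[p]])))
        }
      }
      own_of <- function(tp) match(tp, out_tpos)
      planted_own <- stats::na.omit(c(
        own_of(template$box1_start:(template$box1_start + 2L)),
        own_of(template$box2_start:(template$box2_start + 2L)),
        own_of(c(template$h2_pos, template$h5_pos,
                 template$le1_pos, template$le2_pos)),
        length(out_chars)))
      out_chars <- suppress_decoys(out_chars, protect = planted_own)

      # true pairwise alignment rows (sequence vs template)
      aln_seq_cols <- character(0)
      aln_ref_cols <- character(0)
      i <- 1L
      for (p in seq_len(L)) {
        if (present[p]) {
          aln_seq_cols <- c(aln_seq_cols, out_chars[i]); i <- i + 1L
          aln_ref_cols <- c(aln_ref_cols, tchars[p])
        } else {
          aln_seq_cols <- c(aln_seq_cols, "-")
          aln_ref_cols <- c(aln_ref_cols, tchars[p])
        }
        nins <- length(ins[[p]])
        if (nins) {
          aln_seq_cols <- c(aln_seq_cols, out_chars[i:(i + nins - 1L)])
          i <- i + nins
          aln_ref_cols <- c(aln_ref_cols, rep("-", nins))
        }
      }

      seq_id <- sprintf("%s_sim%03d", template$template_id, k)
      seqs[k] <- chars_seq(out_chars)
      truths[[k]] <- data.frame(
        seq_id = seq_id,
        source_template_id = template$template_id,
        subfamily = template$subfamily_label,
        planted_box1 = substr(template$residues, template$box1_start,
                              template$box1_start + 2L),
        box1_start = own_of(template$box1_start),
        planted_box2 = substr(template$residues, template$box2_start,
                              template$box2_start + 2L),
        box2_start = own_of(template$box2_start),
        planted_filter = paste0(tchars[c(template$h2_pos, template$h5_pos,
                                         template$le1_pos, template$le2_pos)],
                                collapse = ""),
        h2_pos = own_of(template$h2_pos),
        h5_pos = own_of(template$h5_pos),
        le1_pos = own_of(template$le1_pos),
        le2_pos = own_of(template$le2_pos),
        planted_cterm = out_chars[length(out_chars)],
        length = length(out_chars),
        aln_seq = chars_seq(aln_seq_cols),
        aln_ref = chars_seq(aln_ref_cols),
        stringsAsFactors = FALSE)
      names(seqs)[k] <- seq_id
    }
  })
  list(sequences = seqs, truth = do.call(rbind, truths))
}

# The packaged panel layout: 20 heterokont MIPs with the published filter
# strings, motif variants, C-terminal residues and length classes. The
# text enumerates motif variants for ten proteins; the remaining ten are
# carried as conserved NPA pairs.
panel_spec <- function() {
  spec <- utils::read.table(text = "
id     subfamily filter box1 box2 cterm length
TpMIP1 bacterial IAGV NPA NPA S 272
TpMIP2 LIP       WIPL NPA NPM K 294
ToMIP1 LIP       WLPL NPA NPM K 296
ToMIP2 bacterial IAGV NPA NPA S 270
PtMIP1 GIP       WVAR NPA NPA S 285
PtMIP2 GIP       WVGR NPA NPA S 287
PtMIP3 GIP       WVAR NPA NPA S 283
PtMIP4 unclassified FHCR NPG NPA S 279
PtMIP5 LIP       WLPL NPA NPM K 292
NgMIP  LIP       WLPI NPA NPM K 230
SarMIP LIP       WLPL NPA NPM K 286
PnmMIP LIP       WLPL NPA NPM K 288
FcMIP  LIP       WLPL NPA NPM K 290
EsAQP  PIP       FHAR NPA NPA S 278
EsPIP  PIP       FHCR NPA NPA S 276
EsMIP  LIP       WLPI NPA NPM K 225
AaMIP1 LIP       YVPL NPA NPA S 284
AaMIP2 GIP       FICR NPA NPA S 281
AaMIP3 bacterial TASV NPA NPA S 274
AaMIP4 MIPE      FHCR NGA NPA S 282
", header = TRUE, stringsAsFactors = FALSE)
  spec
}

# Contiguous deletion blocks, centred in the flexible inter-feature
# regions, removing `total` scaffold columns. Regions avoid every
# protected window of the scaffold layout.
panel_deletion_columns <- function(total) {
  regions <- list(r3 = 205:265, r2 = 112:138, r1 = 12:48)
  cols <- integer(0)
  left <- total
  for (r in regions) {
    if (left <= 0L) break
    k <- min(left, length(r))
    start <- r[1] + (length(r) - k) %/% 2L
    cols <- c(cols, start:(start + k - 1L))
    left <- left - k
  }
  if (left > 0L) stop("panel deletion budget exceeded", call. = FALSE)
  sort(cols)
}

#' Generate the 20-protein heterokont panel
#'
#' Builds the fixed panel of 20 heterokont MIP sequences whose planted
#' ar/R filters, NPA-box variants, C-terminal residues and length classes
#' encode the published comparison of heterokont MIPs: eight LIP-adjacent
#' proteins carry NPM in place of the second NPA box, AaMIP4 carries NGA
#' in place of the first, PtMIP4 carries NPG, the eight NPM carriers end
#' in lysine, and the nine LIP members have P at LE1 and L/I at LE2.
#' Backgrounds derive from the canonical scaffold through fixed
#' subfamily-level divergence plus seed-dependent member-level variation,
#' so the panel is deterministic given `seed` and remains alignable to the
#' packaged reference annotations for any seed.
#'
#' @param seed integer seed controlling member-level background variation.
#' @return `list(sequences = named character of 20 records,
#'   truth = data.frame of 20 truth rows)`, class `heterokont_panel`.
#' @export
#' @examples
#' panel <- generate_heterokont_panel(seed = 1)
#' panel$truth$planted_filter[panel$truth$seq_id == "PtMIP1"]  # "WVAR"
generate_heterokont_panel <- function(seed) {
  spec <- panel_spec()
  scaffold <- mip_scaffold_template()
  prot <- template_protected_positions(scaffold)
  sites <- setdiff(seq_len(.SCAFFOLD_LEN), c(prot, conserved_columns()))

  seqs <- character(0)
  truths <- vector("list", nrow(spec))
  with_seed(seed, {
    for (k in seq_len(nrow(spec))) {
      row <- spec[k, ]
      tpl <- subfamily_template(row$subfamily)
      chars <- seq_chars(tpl$residues)

      # member-level background variation from the caller's seed
      jitter <- sites[stats::runif(length(sites)) < 0.08]
      for (p in jitter) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
      chars <- suppress_decoys(chars, protect = c(78L, 185L),
                               template = seq_chars(tpl$residues))

      chars <- plant_features(chars, box1_start = 78L, box2_start = 185L,
                              box1 = row$box1, box2 = row$box2,
                              h2_pos = 60L, h5_pos = 175L,
                              le1_pos = 188L, le2_pos = 190L,
                              filter = row$filter, cterm = row$cterm)

      del <- panel_deletion_columns(.SCAFFOLD_LEN - row$length)
      present <- rep(TRUE, .SCAFFOLD_LEN)
      present[del] <- FALSE
      own <- cumsum(present)
      own_of <- function(p) own[p]

      out_chars <- chars[present]
      planted_own <- c(own_of(78:80), own_of(185:187),
                       own_of(c(60L, 175L, 188L, 190L)), length(out_chars))
      out_chars <- suppress_decoys(out_chars, protect = planted_own)

      aln_seq_cols <- ifelse(present, chars, "-")
      # suppression may have rewritten junction residues
      aln_seq_cols[present] <- out_chars

      seqs[row$id] <- chars_seq(out_chars)
      truths[[k]] <- data.frame(
        seq_id = row$id,
        source_template_id = scaffold$template_id,
        subfamily = row$subfamily,
        planted_box1 = row$box1, box1_start = own_of(78L),
        planted_box2 = row$box2, box2_start = own_of(185L),
        planted_filter = row$filter,
        h2_pos = own_of(60L), h5_pos = own_of(175L),
        le1_pos = own_of(188L), le2_pos = own_of(190L),
        planted_cterm = row$cterm,
        length = length(out_chars),
        aln_seq = chars_seq(aln_seq_cols),
        aln_ref = scaffold$residues,
        stringsAsFactors = FALSE)
    }
  })
  structure(list(sequences = seqs, truth = do.call(rbind, truths)),
            class = "heterokont_panel")
}

#' @export
print.heterokont_panel <- function(x, ...) {
  cat(sprintf("Heterokont MIP panel: %d sequences\n", length(x$sequences)))
  print(table(x$truth$subfamily))
  invisible(x)
}

#' Write a simulated set and its truth table to disk
#'
#' Emits `sequences.fasta` and `truth.tsv` under `dir`; the pair
#' round-trips losslessly through [read_truth_tables()].
#'
#' @param x a panel or family (`list(sequences, truth)`).
#' @param dir output directory, created if needed.
#' @return Invisibly, the two file paths.
#' @export
write_truth_tables <- function(x, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  }
  fasta <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "truth.tsv")
  write_fasta(x$sequences, fasta)
  utils::write.table(x$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, truth = tsv))
}

#' Read back a simulated set written by [write_truth_tables()]
#'
#' @param dir directory holding `sequences.fasta` and `truth.tsv`.
#' @return `list(sequences, truth)`.
#' @export
read_truth_tables <- function(dir) {
  fasta <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "truth.tsv")
  for (f in c(fasta, tsv)) {
    if (!file.exists(f)) stop(sprintf("missing file '%s'", f), call. = FALSE)
  }
  seqs <- read_fasta(fasta)
  truth <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                             colClasses = "character")
  for (col in c("box1_start", "box2_start", "h2_pos", "h5_pos",
                "le1_pos", "le2_pos", "length")) {
    truth[[col]] <- as.integer(truth[[col]])
  }
  if (!setequal(names(seqs), truth$seq_id)) {
    stop("FASTA ids and truth table ids disagree", call. = FALSE)
  }
  list(sequences = seqs, truth = truth)
}
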