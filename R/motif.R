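# NPA-box detection and motif-pair classification. The two boxes sit on
# loops B and E of the MIP fold; subfamily-diagnostic variants replace the
# canonical Asn-Pro-Ala with NPM, NPG, NGA and similar tripeptides.

#' Scan a MIP sequence for its two NPA-like boxes
#'
#' Candidate boxes are every occurrence of the pattern N-\[PG\]-X (X any
#' standard residue). The reported pair (i, j), with i starting in the
#' N-terminal 60\% of the sequence and j in the C-terminal 60\%, maximises
#' a preference score (exact NPA scores 2, any other N-\[PG\]-X scores 1,
#' summed) subject to a minimum separation; ties are broken by the
#' smallest i, then the smallest j. When no valid pair exists the best
#' single candidate inside a window is reported and the other box is
#' absent; a sequence with no candidate at all yields both boxes absent
#' plus a warning record. Boxes are never fabricated.
#'
#' @param seqs named character vector of residue strings (or a single
#'   unnamed string), each of length >= 100.
#' @param min_separation minimum residues between box starts (default 40,
#'   three transmembrane helices between loops B and E).
#' @return data.frame with one row per sequence: `seq_id`, `box1`, `pos1`,
#'   `box2`, `pos2` (`NA` for absent boxes), `conserved_pair` (both boxes
#'   exactly NPA), `label` from [classify_motif_pair()], `warning`.
#' @export
#' @examples
#' scan_npa_boxes(c(q = paste0(paste(rep("L", 60), collapse = ""), "NPA",
#'                             paste(rep("G", 60), collapse = ""), "NPM",
#'                             paste(rep("L", 20), collapse = ""))))
scan_npa_boxes <- function(seqs, min_separation = 40) {
  if (is.null(names(seqs))) {
    if (length(seqs) != 1L) stop("multiple sequences must be named", call. = FALSE)
    names(seqs) <- "query"
  }
  assert_standard_aa(seqs, what = "query sequence")
  rows <- lapply(names(seqs), function(id) {
    scan_one(id, seqs[[id]], min_separation)
  })
  do.call(rbind, rows)
}

scan_one <- function(id, s, min_separation) {
  L <- nchar(s)
  if (L < 100) {
    stop(sprintf("sequence '%s' is shorter than 100 residues", id),
         call. = FALSE)
  }
  m <- gregexpr("(?=N[PG][A-Z])", s, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0 & m + 2 <= L])
  none <- data.frame(seq_id = id, box1 = NA_character_, pos1 = NA_integer_,
                     box2 = NA_character_, pos2 = NA_integer_,
                     conserved_pair = FALSE, label = "incomplete",
                     warning = "no NPA-like candidates found",
                     stringsAsFactors = FALSE)
  if (!length(starts)) return(none)

  motif_at <- vapply(starts, function(p) substr(s, p, p + 2), character(1))
  score <- ifelse(motif_at == "NPA", 2L, 1L)
  in_first <- starts <= ceiling(0.6 * L)
  in_second <- starts >= floor(0.4 * L)

  best <- NULL
  for (a in which(in_first)) {
    for (b in which(in_second)) {
      if (starts[b] - starts[a] < min_separation) next
      cand <- c(score[a] + score[b], -starts[a], -starts[b], a, b)
      if (is.null(best) ||
          cand[1] > best[1] ||
          (cand[1] == best[1] && (cand[2] > best[2] ||
           (cand[2] == best[2] && cand[3] > best[3])))) {
        best <- cand
      }
    }
  }
  if (!is.null(best)) {
    a <- best[4]; b <- best[5]
    out <- data.frame(seq_id = id, box1 = motif_at[a], pos1 = starts[a],
                      box2 = motif_at[b], pos2 = starts[b],
                      conserved_pair = motif_at[a] == "NPA" &&
                        motif_at[b] == "NPA",
                      label = NA_character_, warning = "",
                      stringsAsFactors = FALSE)
  } else if (any(in_first)) {
    a <- which(in_first)[which.max(score[in_first])]
    out <- data.frame(seq_id = id, box1 = motif_at[a], pos1 = starts[a],
                      box2 = NA_character_, pos2 = NA_integer_,
                      conserved_pair = FALSE, label = NA_character_,
                      warning = "no second box at the required separation",
                      stringsAsFactors = FALSE)
  } else {
    b <- which(in_second)[which.max(score[in_second])]
    out <- data.frame(seq_id = id, box1 = NA_character_, pos1 = NA_integer_,
                      box2 = motif_at[b], pos2 = starts[b],
                      conserved_pair = FALSE, label = NA_character_,
                      warning = "no first box at the required separation",
                      stringsAsFactors = FALSE)
  }
  out$label <- classify_motif_pair(out)
  out
}

#' Classify a detected NPA-box pair
#'
#' @param pair one row (or several rows) as returned by
#'   [scan_npa_boxes()], or a list with elements `box1` and `box2`.
#' @return Character vector of labels: `canonical` (both NPA),
#'   `second_NPM` (NPA then NPM), `first_variant` (variant first box,
#'   conserved second), `incomplete` (a box absent), otherwise
#'   `other_variant`. Exactly one label per pair.
#' @export
#' @examples
#' classify_motif_pair(list(box1 = "NPA", box2 = "NPM"))  # "second_NPM"
classify_motif_pair <- function(pair) {
  b1 <- pair$box1
  b2 <- pair$box2
  n <- max(length(b1), length(b2))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n)
  vapply(seq_len(n), function(i) {
    if (is.na(b1[i]) || is.na(b2[i])) return("incomplete")
    if (b1[i] == "NPA" && b2[i] == "NPA") return("canonical")
    if (b1[i] == "NPA" && b2[i] == "NPM") return("second_NPM")
    if (b1[i] != "NPA" && b2[i] == "NPA") return("first_variant")
    "other_variant"
  }, character(1))
}
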