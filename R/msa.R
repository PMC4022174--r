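# Multiple-alignment container and operations: validation, terminal
# trimming, aligned-FASTA and Stockholm input, true-alignment assembly
# from simulator truth tables.

#' Coerce to a validated multiple sequence alignment
#'
#' An alignment is represented as a named character vector of equal-length
#' gapped rows over the 20 standard residues plus `-`.
#'
#' @param x named character vector (or list) of gapped rows.
#' @return The validated named character vector with class `mip_msa`.
#' @export
as_msa <- function(x) {
  if (inherits(x, "mip_msa")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x))) {
    stop("alignment rows must carry unique non-empty names", call. = FALSE)
  }
  w <- unique(nchar(x))
  if (length(w) != 1L) {
    bad <- names(x)[nchar(x) != nchar(x)[1]][1]
    stop(sprintf("alignment rows differ in length (row '%s')", bad),
         call. = FALSE)
  }
  assert_standard_aa(x, what = "alignment", allow_gap = TRUE)
  structure(x, class = "mip_msa")
}

#' @export
print.mip_msa <- function(x, ...) {
  cat(sprintf("MSA: %d rows x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

msa_gap_fraction <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  colMeans(m == "-")
}

#' Trim uninformative alignment termini
#'
#' Removes the maximal runs of leading and trailing columns whose gap
#' fraction exceeds `terminal_gap_fraction`; interior columns are never
#' touched. Mirrors the usual manual editing step that discards ragged,
#' non-homologous N- and C-terminal overhangs before distance estimation.
#'
#' @param msa alignment coercible via [as_msa()].
#' @param terminal_gap_fraction columns with a gap fraction strictly above
#'   this are trimmable at the termini (default 0.5).
#' @return The trimmed `mip_msa`. Idempotent.
#' @export
trim_msa <- function(msa, terminal_gap_fraction = 0.5) {
  msa <- as_msa(msa)
  gf <- msa_gap_fraction(msa)
  keep_mask <- gf <= terminal_gap_fraction
  if (!any(keep_mask)) {
    stop(sprintf(
      "trimming at terminal gap fraction %g removes every column",
      terminal_gap_fraction), call. = FALSE)
  }
  first <- which(keep_mask)[1]
  last <- which(keep_mask)[length(which(keep_mask))]
  out <- substr(unclass(msa), first, last)
  names(out) <- names(msa)
  as_msa(out)
}

#' Read an aligned FASTA file
#'
#' @param path aligned-FASTA file; all records must have equal length.
#' @return An `mip_msa`.
#' @export
read_msa_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  as_msa(stats::setNames(as.character(s), names(s)))
}

#' Write an alignment as aligned FASTA
#'
#' @param msa alignment coercible via [as_msa()].
#' @param path output file.
#' @export
write_msa_fasta <- function(msa, path) {
  msa <- as_msa(msa)
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(msa)), path)
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' Minimal reader for the Stockholm 1.0 flat format (the format emitted by
#' profile-HMM aligners): `#` lines and the `//` terminator are skipped,
#' multi-block files are concatenated per sequence id, and `.` gaps are
#' normalised to `-`. Residues are upper-cased.
#'
#' @param path Stockholm file.
#' @return An `mip_msa`.
#' @export
read_msa_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1])) {
    stop(sprintf("'%s' does not look like a Stockholm file", path),
         call. = FALSE)
  }
  rows <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed Stockholm sequence line: '%s'", ln),
           call. = FALSE)
    }
    id <- parts[1]
    rows[[id]] <- paste0(rows[[id]] %||% "", parts[2])
  }
  out <- toupper(unlist(rows))
  out <- chartr(".", "-", out)
  as_msa(out)
}

#' Assemble the true alignment recorded by the simulator
#'
#' Merges the per-sequence pairwise truth alignments (sequence row vs
#' template row) of one truth table into a single MSA, using the shared
#' template coordinate system as the anchor. Insertion columns private to
#' one sequence become all-gap columns in every other row.
#'
#' @param truth a truth table from [generate_family()] or
#'   [generate_heterokont_panel()]. Rows from different templates may be
#'   mixed when the templates share one coordinate system (equal length,
#'   as the packaged scaffold-derived subfamily templates do).
#' @return An `mip_msa` with one row per sequence.
#' @export
build_true_msa <- function(truth) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1)
  aseq <- strsplit(truth$aln_seq, "", fixed = TRUE)
  aref <- strsplit(truth$aln_ref, "", fixed = TRUE)

  # per sequence: number of insertion columns after each template position
  # (template position 0 = before the first column)
  tlen <- sum(aref[[1]] != "-")
  ins_after <- matrix(0L, nrow = nrow(truth), ncol = tlen + 1L)
  for (i in seq_len(nrow(truth))) {
    tpos <- cumsum(aref[[i]] != "-")      # template position per column
    ins <- tabulate(tpos[aref[[i]] == "-"] + 1L, nbins = tlen + 1L)
    if (sum(aref[[i]] != "-") != tlen) {
      stop("truth rows disagree on template length", call. = FALSE)
    }
    ins_after[i, ] <- ins
  }
  width_after <- apply(ins_after, 2, max)

  rows <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sc <- aseq[[i]]
    rc <- aref[[i]]
    tpos <- cumsum(rc != "-")
    out <- character(0)
    # columns grouped by the template position they follow (0..tlen)
    for (p in 0:tlen) {
      grp <- which(tpos == p)
      ins_cols <- grp[rc[grp] == "-"]
      anchor <- grp[rc[grp] != "-"]
      if (p > 0) out <- c(out, sc[anchor])
      pad <- width_after[p + 1L] - length(ins_cols)
      out <- c(out, sc[ins_cols], rep("-", pad))
    }
    rows[i] <- chars_seq(out)
  }
  as_msa(stats::setNames(rows, truth$seq_id))
}
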