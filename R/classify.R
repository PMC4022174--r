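# Subfamily assignment: combines NPA-box variants, the ar/R filter, the
# C-terminal residue and (optionally) tree placement into one call per
# sequence. The LIP subfamily is delineated by its filter signature:
# proline at LE1 together with leucine/isoleucine at LE2, typically
# accompanied by an NPM second box, W/Y at H2 and a C-terminal lysine.

#' Compute the LIP evidence signature
#'
#' Five literal booleans read off the evidence: P at LE1; L or I at LE2;
#' second box NPM; C-terminal lysine; W or Y at H2. The primary LIP
#' criterion is `le1_is_P AND le2_in_LI`; the remaining flags are
#' corroborating. Gapped filter roles evaluate to `FALSE`.
#'
#' @param filter one row of [extract_arr_filter()] output (or any list
#'   with `h2`, `le1`, `le2`).
#' @param boxes one row of [scan_npa_boxes()] output (or a list with
#'   `box2`).
#' @param cterm single C-terminal residue letter (`NA` allowed).
#' @return list of class `lip_signature` with the five booleans and
#'   `primary` (the main criterion).
#' @export
#' @examples
#' lip_signature(list(h2 = "W", le1 = "P", le2 = "L"),
#'               list(box2 = "NPM"), "K")
lip_signature <- function(filter, boxes, cterm) {
  le1 <- filter$le1 %||% "-"
  le2 <- filter$le2 %||% "-"
  h2 <- filter$h2 %||% "-"
  b2 <- boxes$box2 %||% NA_character_
  sig <- list(
    le1_is_P = identical(le1, "P"),
    le2_in_LI = !is.na(le2) && le2 %in% c("L", "I"),
    second_box_NPM = !is.na(b2) && identical(b2, "NPM"),
    cterm_K = !is.na(cterm) && identical(cterm, "K"),
    h2_in_WY = !is.na(h2) && h2 %in% c("W", "Y"))
  sig$primary <- sig$le1_is_P && sig$le2_in_LI
  class(sig) <- "lip_signature"
  sig
}

#' Assign a subfamily from an evidence bundle
#'
#' Rule precedence (first match wins, deterministic):
#' \enumerate{
#'   \item LIP primary criterion (LE1 = P and LE2 in \{L, I\}) ->
#'     \code{LIP}. Tree-independent; a conflicting tree placement is
#'     logged in the evidence trail, the filter signature wins.
#'   \item Tree present and the query monophyletic with exactly one
#'     labelled reference group at support >= \code{support_threshold}
#'     -> that group's label.
#'   \item Filter rule G (glycerol permease) -> \code{GIP}.
#'   \item Filter rule W (water) -> \code{PIP} or \code{MIPE}, separable
#'     only by tree evidence; without it the call is
#'     \code{unclassified} with both candidates recorded.
#'   \item Otherwise \code{unclassified}.
#' }
#'
#' @param seq_id sequence identifier.
#' @param filter one row of [extract_arr_filter()] output.
#' @param boxes one row of [scan_npa_boxes()] output.
#' @param cterm C-terminal residue letter.
#' @param tree optional `phylo` tree containing `seq_id` and reference
#'   leaves.
#' @param reference_labels optional named character vector mapping
#'   reference leaf -> subfamily label (PIP, GIP, MIPE, LIP, SIP, MIPC,
#'   bacterial).
#' @param support_threshold minimum clade support (percent) for
#'   tree-based assignment; default 50.
#' @return data.frame row with `seq_id`, `subfamily`, `specificity`,
#'   `rule_id`, `clade_support`, and a non-empty `evidence` trail
#'   (semicolon-joined `rule:detail` items).
#' @export
assign_subfamily <- function(seq_id, filter, boxes, cterm,
                             tree = NULL, reference_labels = NULL,
                             support_threshold = 50) {
  known <- c("PIP", "GIP", "MIPE", "LIP", "SIP", "MIPC", "bacterial")
  if (!is.null(reference_labels)) {
    bad <- setdiff(unique(reference_labels), known)
    if (length(bad)) {
      stop(sprintf("unknown reference subfamily label '%s'", bad[1]),
           call. = FALSE)
    }
  }
  spec <- infer_specificity(filter$filter)
  sig <- lip_signature(filter, boxes, cterm)
  ev <- c(sprintf("filter:%s", filter$filter),
          sprintf("boxes:%s/%s", boxes$box1 %||% NA, boxes$box2 %||% NA),
          sprintf("specificity:%s(rule %s)", spec$specificity, spec$rule_id))

  placement <- NULL
  if (!is.null(tree) && !is.null(reference_labels) &&
      seq_id %in% tree$tip.label) {
    for (grp in unique(reference_labels)) {
      members <- names(reference_labels)[reference_labels == grp]
      members <- intersect(members, tree$tip.label)
      if (length(members) < 1) next
      res <- tryCatch(is_monophyletic(tree, c(seq_id, members)),
                      error = function(e) NULL)
      if (!is.null(res) && res$monophyletic &&
          !is.na(res$support) && res$support >= support_threshold) {
        cand <- list(group = grp, support = res$support)
        if (is.null(placement) || cand$support > placement$support) {
          placement <- cand
        }
      }
    }
    if (!is.null(placement)) {
      ev <- c(ev, sprintf("tree:clusters with %s at %d%%",
                          placement$group, as.integer(placement$support)))
    }
  }

  subfamily <- "unclassified"
  support <- NA_real_
  if (sig$primary) {
    subfamily <- "LIP"
    ev <- c(ev, sprintf(
      "lip_signature:LE1=P,LE2 in {L,I} (NPM=%s, ctermK=%s, H2 W/Y=%s)",
      sig$second_box_NPM, sig$cterm_K, sig$h2_in_WY))
    if (!is.null(placement) && placement$group != "LIP") {
      ev <- c(ev, sprintf(
        "conflict:tree places with %s but LIP filter signature wins",
        placement$group))
    } else if (!is.null(placement)) {
      support <- placement$support
    }
  } else if (!is.null(placement)) {
    subfamily <- placement$group
    support <- placement$support
  } else if (spec$rule_id == "G") {
    subfamily <- "GIP"
    ev <- c(ev, "filter_rule:G (glycerol permease signature)")
  } else if (spec$rule_id == "W") {
    subfamily <- "unclassified"
    ev <- c(ev, "ambiguous:water filter fits PIP and MIPE; tree evidence needed")
  } else {
    ev <- c(ev, "no rule matched")
  }

  data.frame(seq_id = seq_id, subfamily = subfamily,
             specificity = spec$specificity, rule_id = spec$rule_id,
             clade_support = support,
             evidence = paste(ev, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Classify a set of sequences end to end
#'
#' Convenience wrapper: scans boxes, extracts filters and assigns
#' subfamilies for every sequence.
#'
#' @param seqs named character vector of residue strings.
#' @param refs reference table (packaged default).
#' @param tree,reference_labels,support_threshold forwarded to
#'   [assign_subfamily()].
#' @param min_separation forwarded to [scan_npa_boxes()].
#' @return data.frame of subfamily calls, one row per sequence.
#' @export
classify_sequences <- function(seqs, refs = load_mip_references(),
                               tree = NULL, reference_labels = NULL,
                               support_threshold = 50, min_separation = 40) {
  boxes <- scan_npa_boxes(seqs, min_separation = min_separation)
  filters <- extract_arr_filter(seqs, refs = refs)
  calls <- lapply(names(seqs), function(id) {
    assign_subfamily(
      id,
      filter = filters[filters$seq_id == id, , drop = FALSE],
      boxes = boxes[boxes$seq_id == id, , drop = FALSE],
      cterm = substr(seqs[[id]], nchar(seqs[[id]]), nchar(seqs[[id]])),
      tree = tree, reference_labels = reference_labels,
      support_threshold = support_threshold)
  })
  do.call(rbind, calls)
}

#' Summarise subfamily calls
#'
#' @param calls data.frame from [classify_sequences()] or
#'   [assign_subfamily()] rows.
#' @return list with `n`, `by_subfamily` and `by_specificity` count
#'   tables (stable, C-locale ordering).
#' @export
summarize_calls <- function(calls) {
  stopifnot(is.data.frame(calls), nrow(calls) >= 1)
  if (any(!nzchar(calls$evidence))) {
    stop("subfamily calls with empty evidence are invalid", call. = FALSE)
  }
  count_by <- function(x) {
    tb <- table(x)
    tb[stable_order(names(tb))]
  }
  list(n = nrow(calls),
       by_subfamily = count_by(calls$subfamily),
       by_specificity = count_by(calls$specificity))
}
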