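# End-to-end pipeline: simulate/load -> validate -> motif scan -> filter
# extraction -> alignment/tree with bootstrap -> classification ->
# summary, driven by one config with explicit seeds, writing every stage
# output plus a run manifest.

default_config <- function() {
  list(
    input = list(simulate = list(what = "panel", seed = NULL)),
    reference = "packaged",
    msa = "true-alignment",
    bootstrap_reps = 100,
    bootstrap_seed = NULL,
    min_separation = 40,
    trim_threshold = 0.5,
    support_threshold = 50,
    labels = NULL,
    outdir = NULL)
}

#' Load and validate a pipeline run configuration
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Unknown keys are rejected; every random stage must carry an explicit
#'   seed.
#' @return The merged, validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown config key '%s'", unknown[1]), call. = FALSE)
  }
  cfg <- utils::modifyList(base, config)
  if ("input" %in% names(config)) {
    # the input source is one alternative, not a set of mergeable defaults
    cfg$input <- config$input
  }
  if (is.null(cfg$outdir)) {
    stop("config field 'outdir' is required", call. = FALSE)
  }
  sim <- cfg$input$simulate
  if (!is.null(sim) && is.null(sim$seed)) {
    stop("config field 'input.simulate.seed' is required", call. = FALSE)
  }
  if (is.null(sim) && is.null(cfg$input$fasta)) {
    stop("config field 'input' needs either 'fasta' or 'simulate'",
         call. = FALSE)
  }
  if (cfg$bootstrap_reps > 0 && !identical(cfg$msa, "none") &&
      is.null(cfg$bootstrap_seed)) {
    stop("config field 'bootstrap_seed' is required", call. = FALSE)
  }
  cfg
}

#' Validate pipeline input files
#'
#' Checks FASTA, alignment, reference-table and label files for standard
#' alphabet, consistent row lengths and duplicate ids, separating fatal
#' errors from warnings.
#'
#' @param paths named list with any of `fasta`, `msa`, `reference`,
#'   `labels`.
#' @return list with `records` (per-file record counts), `warnings`;
#'   fatal problems raise errors naming the offender.
#' @export
validate_inputs <- function(paths) {
  records <- list()
  warnings <- character(0)
  if (!is.null(paths$fasta)) {
    seqs <- read_fasta(paths$fasta)
    if (anyDuplicated(names(seqs))) {
      stop(sprintf("duplicate sequence id '%s' in '%s'",
                   names(seqs)[duplicated(names(seqs))][1], paths$fasta),
           call. = FALSE)
    }
    assert_standard_aa(seqs, what = sprintf("FASTA '%s'", paths$fasta))
    if (any(nchar(seqs) < 100)) {
      warnings <- c(warnings, "sequences shorter than 100 residues present")
    }
    records$fasta <- length(seqs)
  }
  if (!is.null(paths$msa)) {
    msa <- if (grepl("\\.(sto|stk|stockholm)$", paths$msa)) {
      read_msa_stockholm(paths$msa)
    } else {
      read_msa_fasta(paths$msa)
    }
    records$msa <- length(msa)
  }
  if (!is.null(paths$reference)) {
    refs <- load_mip_references(paths$reference)
    records$reference <- nrow(refs)
  }
  if (!is.null(paths$labels)) {
    lab <- read_tsv(paths$labels)
    if (!all(c("leaf", "subfamily") %in% names(lab))) {
      stop(sprintf("label table '%s' needs columns leaf, subfamily",
                   paths$labels), call. = FALSE)
    }
    records$labels <- nrow(lab)
  }
  list(records = records, warnings = warnings)
}

#' Run the full classification pipeline
#'
#' Executes the stages in fixed order — obtain sequences (simulated panel
#' or family, or a FASTA file), validate, scan NPA boxes, extract ar/R
#' filters, build or load the alignment, trim termini, estimate JTT
#' distances, build the NJ tree with bootstrap supports, classify, and
#' summarise — writing each stage's output under `outdir` before the
#' next stage starts. Reruns with an identical config produce
#' byte-identical TSV/JSON/Newick outputs. A failing stage halts the run;
#' the manifest records the failing stage either way.
#'
#' @param config config list or YAML path (see [load_run_config()]).
#' @return The run manifest (list), invisibly containing config echo,
#'   package version, data-file checksums, per-stage record counts and
#'   warnings.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  data_files <- c(
    system.file("extdata", "jtt_exchangeabilities.tsv", package = "mipclass"),
    system.file("extdata", "jtt_frequencies.tsv", package = "mipclass"),
    system.file("extdata", "mip_references_synthetic.tsv", package = "mipclass"))
  manifest <- list(
    config = cfg,
    package_version = as.character(utils::packageVersion("mipclass")),
    data_checksums = as.list(stats::setNames(unname(tools::md5sum(data_files)),
                                             basename(data_files))),
    stages = list(), counts = list(), warnings = character(0),
    status = "running", failed_stage = NA_character_)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }
  on.exit(flush_manifest())

  stage <- function(name, fun) {
    manifest$failed_stage <<- name
    out <- fun()
    manifest$stages[[length(manifest$stages) + 1L]] <<- name
    manifest$failed_stage <<- NA_character_
    out
  }

  result <- tryCatch({
    truth <- NULL
    seqs <- stage("input", function() {
      sim <- cfg$input$simulate
      if (!is.null(sim)) {
        obj <- if (identical(sim$what, "panel")) {
          generate_heterokont_panel(seed = sim$seed)
        } else {
          generate_family(mip_scaffold_template(), n = sim$n %||% 20,
                          divergence = sim$divergence %||% 0.2,
                          indel_rate = sim$indel_rate, seed = sim$seed)
        }
        truth <<- obj$truth
        write_truth_tables(obj, cfg$outdir)
        obj$sequences
      } else {
        read_fasta(cfg$input$fasta)
      }
    })
    manifest$counts$sequences <- length(seqs)

    stage("validate", function() {
      if (anyDuplicated(names(seqs))) {
        stop(sprintf("duplicate sequence id '%s'",
                     names(seqs)[duplicated(names(seqs))][1]), call. = FALSE)
      }
      assert_standard_aa(seqs, what = "input sequences")
    })

    boxes <- stage("scan", function() {
      b <- scan_npa_boxes(seqs, min_separation = cfg$min_separation)
      write_tsv(b, file.path(cfg$outdir, "scan.tsv"))
      b
    })
    manifest$counts$scan <- nrow(boxes)
    manifest$warnings <- c(manifest$warnings,
                           boxes$warning[nzchar(boxes$warning)])

    refs <- if (identical(cfg$reference, "packaged")) {
      load_mip_references()
    } else {
      load_mip_references(cfg$reference)
    }
    filters <- stage("filter_extract", function() {
      f <- extract_arr_filter(seqs, refs = refs)
      f$specificity <- infer_specificity(f)$specificity
      f$rule_id <- infer_specificity(f)$rule_id
      write_tsv(f, file.path(cfg$outdir, "filters.tsv"))
      f
    })
    manifest$counts$filters <- nrow(filters)

    tree <- NULL
    if (!identical(cfg$msa, "none")) {
      msa <- stage("msa", function() {
        m <- if (identical(cfg$msa, "true-alignment")) {
          if (is.null(truth)) {
            stop("msa = 'true-alignment' requires simulated input",
                 call. = FALSE)
          }
          build_true_msa(truth)
        } else if (grepl("\\.(sto|stk|stockholm)$", cfg$msa)) {
          read_msa_stockholm(cfg$msa)
        } else {
          read_msa_fasta(cfg$msa)
        }
        m <- trim_msa(m, terminal_gap_fraction = cfg$trim_threshold)
        write_msa_fasta(m, file.path(cfg$outdir, "msa.fasta"))
        m
      })
      manifest$counts$msa_rows <- length(msa)

      tree <- stage("tree", function() {
        D <- jtt_dist_matrix(msa)
        write_tsv(cbind(id = rownames(D), as.data.frame(D)),
                  file.path(cfg$outdir, "distances.tsv"))
        tr <- if (cfg$bootstrap_reps > 0) {
          bootstrap_supports(msa, n_reps = cfg$bootstrap_reps,
                             seed = cfg$bootstrap_seed)
        } else {
          nj_tree(D)
        }
        write_tree_newick(tr, file.path(cfg$outdir, "tree.nwk"))
        tr
      })
    }

    reference_labels <- NULL
    if (!is.null(cfg$labels)) {
      lab <- read_tsv(cfg$labels)
      reference_labels <- stats::setNames(lab$subfamily, lab$leaf)
    }
    calls <- stage("classify", function() {
      cl <- classify_sequences(seqs, refs = refs, tree = tree,
                               reference_labels = reference_labels,
                               support_threshold = cfg$support_threshold,
                               min_separation = cfg$min_separation)
      write_tsv(cl, file.path(cfg$outdir, "calls.tsv"))
      cl
    })
    manifest$counts$calls <- nrow(calls)

    stage("summary", function() {
      s <- summarize_calls(calls)
      jsonlite::write_json(
        list(n = s$n,
             by_subfamily = as.list(s$by_subfamily),
             by_specificity = as.list(s$by_specificity)),
        file.path(cfg$outdir, "summary.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
    manifest$status <- "ok"
    TRUE
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    flush_manifest()
    stop(e)
  })

  flush_manifest()
  invisible(manifest)
}
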