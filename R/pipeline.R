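#' Pipeline configuration with published defaults
#'
#' Central knob set for the end-to-end runs; all defaults are the values the
#' regulon-calling and resequencing filters were run with, and unknown keys
#' are rejected so a typo cannot silently fall back to a default.
#'
#' @param ... Overrides for: `pattern_spec` ("paper-union"), `max_upstream`
#'   (200 bp), `consensus_threshold` (1.0), `require_annotation` (TRUE),
#'   `deny_list`, `circular` (FALSE), `min_reads` (10), `min_frac` (0.20),
#'   `max_span` (10000 bp), `min_overlap` (15 bp), `extinction_coeff`
#'   (6.22 mM^-1 cm^-1), `path_length` (1 cm), `growth_window` (5 points),
#'   `growth_min_r2` (0.98), `reference_target` ("recA").
#' @return A named list of class `rex_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pattern_spec = "paper-union",
    max_upstream = 200,
    consensus_threshold = 1.0,
    require_annotation = TRUE,
    deny_list = c("hypothetical protein", ""),
    circular = FALSE,
    min_reads = 10,
    min_frac = 0.20,
    max_span = 10000,
    min_overlap = 15,
    extinction_coeff = 6.22,
    path_length = 1,
    growth_window = 5,
    growth_min_r2 = 0.98,
    reference_target = "recA"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0 || (length(overrides) > 0 && is.null(names(overrides)))) {
    abort(sprintf("unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "rex_config_error")
  }
  cfg[names(overrides)] <- overrides
  for (nm in c("max_upstream", "min_reads", "min_frac", "max_span",
               "min_overlap", "extinction_coeff", "path_length",
               "growth_window", "growth_min_r2")) {
    assert_scalar_number(cfg[[nm]], nm, min = 0)
  }
  if (cfg$consensus_threshold <= 0.5 || cfg$consensus_threshold > 1) {
    abort("`consensus_threshold` must be in (0.5, 1].",
          class = "rex_config_error")
  }
  structure(cfg, class = "rex_pipeline_config")
}

#' Run the site-prediction stage end to end
#'
#' scan -> annotate -> distance filter -> annotation filter -> consensus ->
#' report, with per-stage record counts logged as messages. Writes
#' `regulon_report.tsv`, `consensus.txt` and `consensus_counts.tsv` into
#' `out_dir`.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to the gene features (GFF3 or TSV).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report` (the filtered annotated site
#'   tibble), `consensus` (a [build_consensus()] object or `NULL` when no
#'   site survived) and `counts` (named per-stage record counts).
#' @export
run_scan <- function(fasta, gff, out_dir, config = pipeline_config()) {
  if (!inherits(config, "rex_pipeline_config")) {
    abort("`config` must come from pipeline_config().",
          class = "rex_config_error")
  }
  for (path in c(fasta, gff)) {
    if (!file.exists(path)) {
      abort(sprintf("input file not found: '%s'.", path),
            class = "rex_input_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  p <- compile_pattern(config$pattern_spec)
  sites <- scan_genome(fasta, p, circular = config$circular)
  inform(sprintf("scan: %d raw hit(s).", nrow(sites)))

  features <- read_gene_features(gff)
  ann <- annotate_sites(sites, features)
  inform(sprintf("annotate: %d site(s) upstream of a gene.", nrow(ann)))

  within_dist <- filter_sites(ann, max_upstream = config$max_upstream,
                              require_annotation = FALSE)
  inform(sprintf("distance filter (<= %d bp): %d site(s).",
                 as.integer(config$max_upstream), nrow(within_dist)))
  kept <- filter_sites(within_dist, max_upstream = config$max_upstream,
                       require_annotation = config$require_annotation,
                       deny_list = config$deny_list)
  inform(sprintf("annotation filter: %d site(s) retained.", nrow(kept)))

  consensus <- NULL
  if (nrow(kept) > 0) {
    consensus <- build_consensus(orient_site(kept),
                                 threshold = config$consensus_threshold)
    writeLines(consensus$consensus, file.path(out_dir, "consensus.txt"))
    counts_df <- as_tibble(t(consensus$counts))
    counts_df <- mutate(counts_df, position = row_number(), .before = 1)
    readr::write_tsv(counts_df, file.path(out_dir, "consensus_counts.tsv"))
  }
  write_regulon_report(kept, file.path(out_dir, "regulon_report.tsv"))

  invisible(list(
    report = kept,
    consensus = consensus,
    counts = c(raw = nrow(sites), annotated = nrow(ann),
               within_distance = nrow(within_dist), retained = nrow(kept))
  ))
}

#' Run a configured subset of pipeline stages
#'
#' Executes any subset of the `scan`, `variants` and `physiology` stages over
#' the supplied inputs and writes a JSON run manifest (inputs, seed, package
#' version, parameter values, per-stage status) for reproducibility. An empty
#' stage list writes the manifest only. If any stage fails, the manifest
#' still records every stage's status and an error of class
#' `rex_stage_error` is raised at the end.
#'
#' @param stages Character subset of `c("scan", "variants", "physiology")`.
#' @param inputs Named list of paths: `fasta`, `gff` (scan); `breakpoints`,
#'   optionally `variants_sample`, `variants_control` (variants);
#'   optionally `fermentation`, `od`, `qpcr_samples`, `qpcr_standards`
#'   (physiology). CSV/TSV as produced by the generators.
#' @param out_dir Output directory; refuses to overwrite a non-empty one
#'   unless `force = TRUE`.
#' @param config A [pipeline_config()].
#' @param seed Integer recorded in the manifest.
#' @param force Overwrite an existing non-empty `out_dir`?
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(stages = character(0), inputs = list(), out_dir,
                    config = pipeline_config(), seed = NA_integer_,
                    force = FALSE) {
  bad <- setdiff(stages, c("scan", "variants", "physiology"))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage(s): %s.", paste(bad, collapse = ", ")),
          class = "rex_config_error")
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf("output directory '%s' is not empty; use force = TRUE.",
                  out_dir), class = "rex_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  status <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch({ fn(); "ok" },
                    error = function(e) paste0("failed: ", conditionMessage(e)))
    status[[name]] <<- res
  }

  if ("scan" %in% stages) {
    run_stage("scan", function() {
      run_scan(inputs$fasta, inputs$gff, out_dir, config)
    })
  }
  if ("variants" %in% stages) {
    run_stage("variants", function() {
      bp <- readr::read_tsv(inputs$breakpoints, show_col_types = FALSE)
      kept <- filter_breakpoints(bp, config$min_reads, config$min_frac)
      readr::write_tsv(kept, file.path(out_dir, "breakpoints_filtered.tsv"))
      calls <- pair_breakpoints(filter(kept, .data$side == "left"),
                                filter(kept, .data$side == "right"),
                                max_span = config$max_span,
                                min_overlap = config$min_overlap)
      readr::write_tsv(calls, file.path(out_dir, "sv_calls.tsv"))
      if (!is.null(inputs$variants_sample) && !is.null(inputs$variants_control)) {
        kept_v <- subtract_background(read_variants(inputs$variants_sample),
                                      read_variants(inputs$variants_control))
        readr::write_tsv(kept_v, file.path(out_dir, "variants_filtered.tsv"))
      }
    })
  }
  if ("physiology" %in% stages) {
    run_stage("physiology", function() {
      wrote <- FALSE
      if (!is.null(inputs$fermentation)) {
        ferm <- readr::read_csv(inputs$fermentation, show_col_types = FALSE)
        readr::write_csv(percent_theoretical_yield(ferm),
                         file.path(out_dir, "yields.csv"))
        wrote <- TRUE
      }
      if (!is.null(inputs$od)) {
        od <- readr::read_csv(inputs$od, show_col_types = FALSE)
        readr::write_csv(fit_growth_curves(od, window = config$growth_window,
                                           min_r2 = config$growth_min_r2),
                         file.path(out_dir, "growth_rates.csv"))
        wrote <- TRUE
      }
      if (!is.null(inputs$qpcr_samples) && !is.null(inputs$qpcr_standards)) {
        curve <- fit_standard_curve(
          readr::read_csv(inputs$qpcr_standards, show_col_types = FALSE))
        expr <- quantify_and_normalize(
          readr::read_csv(inputs$qpcr_samples, show_col_types = FALSE),
          curve, reference_target = config$reference_target)
        readr::write_csv(expr, file.path(out_dir, "expression_ratios.csv"))
        wrote <- TRUE
      }
      if (!wrote) abort("physiology stage given no inputs.",
                        class = "rex_input_error")
    })
  }

  manifest <- list(
    package = "rexreg",
    version = as.character(utils::packageVersion("rexreg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stages = as.list(if (length(status)) status else setNames(list(), character(0))),
    inputs = inputs,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  failed <- names(status)[vapply(status, function(s) s != "ok", TRUE)]
  if (length(failed) > 0) {
    abort(sprintf("stage(s) failed: %s (see manifest).",
                  paste(failed, collapse = ", ")),
          class = "rex_stage_error")
  }
  invisible(manifest)
}
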