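#' Validate a pipeline run configuration
#'
#' A run config is a named list (typically read from a TOML-dialect file
#' via [read_toml_config()]) selecting inputs, outputs and parameter
#' overrides for [run_pipeline()]. Recognized keys: `counts`, `groups`,
#' `gtf`, `fasta` (input paths), `out_dir` (output directory), `assay`
#' (bundled assay name or config path), `discover` (logical; rerun marker
#' discovery instead of using the assay panel), `tau_female`, `tau_male`,
#' `max_mismatch`, `max_len`, `seed`.
#'
#' @param cfg Named list.
#' @return The config with defaults filled in; errors on missing inputs
#'   before any computation starts.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(assay = "bovine_chrY", discover = FALSE,
                   tau_female = NULL, tau_male = NULL,
                   max_mismatch = 0, max_len = 5000, seed = 1L,
                   out_dir = ".")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (is.null(cfg$counts) && is.null(cfg$fasta)) {
    stop("config must provide 'counts' (RNA-seq arm) and/or 'fasta' ",
         "(PCR arm)", call. = FALSE)
  }
  for (k in c("counts", "groups", "gtf", "fasta")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("input path for '", k, "' does not exist: ", cfg[[k]],
           call. = FALSE)
    }
  }
  if (isTRUE(cfg$discover) &&
      (is.null(cfg$counts) || is.null(cfg$groups) || is.null(cfg$gtf))) {
    stop("discovery needs 'counts', 'groups' and 'gtf'", call. = FALSE)
  }
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(cfg$out_dir)) {
      stop("cannot create out_dir: ", cfg$out_dir, call. = FALSE)
    }
  }
  cfg
}

#' Run the sexing pipeline end to end
#'
#' RNA-seq arm: counts -> TMM/CPM -> (optional marker discovery) ->
#' cumulative-CPM sex calls. PCR arm: FASTA templates -> in-silico
#' multiplex -> band-pattern calls. Either arm runs alone if only its
#' inputs are configured. Reports are written under `out_dir`; the exit
#' status distinguishes fully determinate runs (0) from runs containing
#' ambiguous or indeterminate calls (3), so pipelines can route such
#' samples to the other assay.
#'
#' @param cfg Run configuration list, validated by [validate_run_config()].
#' @return List with `status` (0 or 3), `rna` (sex-call report or NULL),
#'   `pcr` (list of multiplex results or NULL), `panel`, `files` (paths
#'   written).
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  assay <- if (inherits(cfg$assay, "assay_definition")) cfg$assay
           else read_assay_definition(cfg$assay)
  panel <- assay$panel
  if (!is.null(cfg$tau_female) || !is.null(cfg$tau_male)) {
    panel <- marker_panel(panel$gene_ids,
                          tau_female = cfg$tau_female %||% panel$tau_female,
                          tau_male = cfg$tau_male %||% panel$tau_male)
  }
  files <- character()
  rna <- NULL
  pcr <- NULL

  if (!is.null(cfg$counts)) {
    counts <- read_count_matrix(cfg$counts)
    factors <- tmm_norm_factors(counts)
    cpm <- cpm_matrix(counts, factors)
    if (isTRUE(cfg$discover)) {
      annots <- read_gene_annotation(cfg$gtf)
      groups <- align_sample_groups(counts, read_sample_groups(cfg$groups))
      disc <- discover_markers(counts, annots, groups)
      panel <- marker_panel(disc$panel$gene_ids,
                            tau_female = panel$tau_female,
                            tau_male = panel$tau_male)
      rp <- file.path(cfg$out_dir, "discovery_report.tsv")
      discovery_report(disc$scores, panel, rp, annots)
      files <- c(files, discovery = rp)
    }
    calls <- sex_calls(cpm, panel)
    cp <- file.path(cfg$out_dir, "calls.tsv")
    rna <- sex_report(calls, cp)
    fp <- file.path(cfg$out_dir, "norm_factors.tsv")
    write_norm_factors(factors, fp)
    files <- c(files, calls = cp, factors = fp)
  }

  if (!is.null(cfg$fasta)) {
    seqs <- read_fasta(cfg$fasta)
    pcr <- lapply(names(seqs), function(sid) {
      simulate_multiplex(seqs[[sid]], assay, max_len = cfg$max_len,
                         max_mismatch = cfg$max_mismatch,
                         template_id = sid)
    })
    names(pcr) <- names(seqs)
    bands <- do.call(rbind, lapply(pcr, `[[`, "bands"))
    bp <- file.path(cfg$out_dir, "bands.tsv")
    utils::write.table(bands, bp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pcalls <- data.frame(
      template_id = names(pcr),
      call = vapply(pcr, `[[`, character(1L), "call"),
      stringsAsFactors = FALSE)
    pp <- file.path(cfg$out_dir, "pcr_calls.tsv")
    utils::write.table(pcalls, pp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, bands = bp, pcr_calls = pp)
  }

  undetermined <- FALSE
  if (!is.null(rna)) undetermined <- rna$tally[["n_ambiguous"]] > 0
  if (!is.null(pcr)) {
    undetermined <- undetermined ||
      any(vapply(pcr, `[[`, character(1L), "call") == "indeterminate")
  }
  summary <- list(status = if (undetermined) 3L else 0L,
                  rna = rna, pcr = pcr, panel = panel, files = files)
  jp <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(
    list(status = summary$status,
         rna_tally = if (!is.null(rna)) as.list(rna$tally) else NULL,
         pcr_calls = if (!is.null(pcr)) {
           lapply(pcr, `[[`, "call")
         } else NULL,
         panel = panel$gene_ids,
         tau_female = panel$tau_female, tau_male = panel$tau_male),
    jp, auto_unbox = TRUE, digits = NA, null = "null")
  summary$files <- c(summary$files, report = jp)
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a
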