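#' Discovery configuration
#'
#' Parameters of the systematic search for chromosome-Y genes expressed
#' exclusively in males. Defaults encode the published procedure: the
#' ampliconic-region search window (nt 6,953,027-15,591,347 of the cattle
#' chromosome-Y assembly), an abundance filter keeping genes with strictly
#' more than 600 raw reads summed over all samples, and male-specificity
#' thresholds motivated by the observed extremes in tissues (female maximum
#' 0.37 CPM, male minimum 30.92 CPM).
#'
#' @param window_start,window_end Coordinate window on chromosome Y, 1-based
#'   inclusive.
#' @param min_total_reads Raw-count total a gene must strictly exceed.
#' @param scale_min_reads_per_sample When `TRUE`, `min_total_reads` is
#'   interpreted per 64 samples and rescaled to the actual sample count
#'   (about 9.4 reads/sample); default keeps the absolute threshold.
#' @param max_offsex_cpm Maximum CPM tolerated in any female sample.
#' @param min_onsex_cpm Minimum CPM required in every male sample.
#' @param top_k Panel size.
#' @param prior_cpm Pseudo-abundance added when displaying log2 fold
#'   changes; never used in the test statistic.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(window_start = 6953027, window_end = 15591347,
                             min_total_reads = 600,
                             scale_min_reads_per_sample = FALSE,
                             max_offsex_cpm = 1.0, min_onsex_cpm = 10.0,
                             top_k = 4, prior_cpm = 0.25) {
  stopifnot(window_start <= window_end, min_total_reads >= 0,
            max_offsex_cpm < min_onsex_cpm, top_k >= 1, prior_cpm >= 0)
  structure(list(window_start = window_start, window_end = window_end,
                 min_total_reads = min_total_reads,
                 scale_min_reads_per_sample = isTRUE(scale_min_reads_per_sample),
                 max_offsex_cpm = max_offsex_cpm,
                 min_onsex_cpm = min_onsex_cpm,
                 top_k = top_k, prior_cpm = prior_cpm),
            class = "discovery_config")
}

#' Drop genes below an abundance threshold
#'
#' Keeps gene rows whose raw-count total across all samples is strictly
#' greater than `min_total_reads`.
#'
#' @param counts Validated count matrix.
#' @param min_total_reads Threshold (strict inequality).
#' @return The filtered count matrix (possibly zero rows).
#' @export
filter_low_count_genes <- function(counts, min_total_reads = 600) {
  counts <- validate_count_matrix(counts)
  keep <- rowSums(counts) > min_total_reads
  if (!any(keep)) message("no genes exceed ", min_total_reads, " total reads")
  counts[keep, , drop = FALSE]
}

# Negative-binomial log-likelihood with per-sample means; mu = 0 is legal
# (probability mass 1 at 0) so all-zero female groups stay finite.
.nb_ll <- function(y, mu, size) {
  ll <- numeric(length(y))
  z <- mu == 0
  ll[z] <- ifelse(y[z] == 0, 0, -Inf)
  ll[!z] <- stats::dnbinom(y[!z], size = size, mu = mu[!z], log = TRUE)
  sum(ll)
}

#' Two-group negative-binomial scoring of every gene
#'
#' A per-gene likelihood-ratio test of a group (sex) effect under a
#' negative-binomial model with effective-library-size offsets. Group means
#' are quasi-ML proportions (group count total over group effective-size
#' total); the dispersion is a pooled within-group method-of-moments
#' estimate, floored at 1e-8 so Poisson-exact fits cannot produce infinite
#' statistics. The statistic is compared against a chi-square with one
#' degree of freedom. This is a deliberately simple single-purpose ranking
#' statistic, not a re-implementation of the quasi-likelihood empirical-Bayes
#' machinery of general differential-expression packages.
#'
#' @param counts Validated count matrix.
#' @param groups Named vector mapping every sample to one of exactly two
#'   labels; when the labels are `male`/`female` the fold change is oriented
#'   male over female, otherwise the first label in sorted order is the
#'   "on" group.
#' @param norm_factors Named normalization factors (defaults to unit).
#' @param prior_cpm Pseudo-abundance for the displayed log2 fold change.
#' @param lib_size Optional named library sizes; supply these when scoring a
#'   subset of genes so that offsets and CPM stay on the full-matrix scale.
#' @return A data.frame sorted by descending score with columns `gene_id`,
#'   `logFC`, `logCPM`, `score`, `p_value`, `max_offsex_cpm`
#'   (largest CPM among "off" (female) samples), `min_onsex_cpm` (smallest
#'   CPM among "on" (male) samples).
#' @export
nb_group_score <- function(counts, groups, norm_factors = NULL,
                           prior_cpm = 0.25, lib_size = NULL) {
  counts <- validate_count_matrix(counts)
  groups <- align_sample_groups(counts, groups)
  labs <- sort(unique(groups))
  if (length(labs) != 2L) {
    stop("exactly two group labels required, got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  on_lab <- if (all(c("male", "female") %in% labs)) "male" else labs[1L]
  off_lab <- setdiff(labs, on_lab)
  lib <- if (is.null(lib_size)) library_sizes(counts)
         else lib_size[colnames(counts)]
  if (anyNA(lib)) stop("lib_size must cover all samples", call. = FALSE)
  if (is.null(norm_factors)) {
    norm_factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  eff <- lib * norm_factors[colnames(counts)]
  cpm <- sweep(counts, 2L, eff, "/") * 1e6
  is_on <- groups == on_lab

  n_on <- sum(eff[is_on])
  n_off <- sum(eff[!is_on])
  n_all <- sum(eff)

  score_one <- function(y) {
    p_on <- sum(y[is_on]) / n_on
    p_off <- sum(y[!is_on]) / n_off
    p_null <- sum(y) / n_all
    mu_alt <- ifelse(is_on, p_on, p_off) * eff
    mu_null <- p_null * eff
    # pooled within-group moment estimate of dispersion (var = mu + d*mu^2)
    nz <- mu_alt > 0
    d <- if (any(nz)) {
      sum((y[nz] - mu_alt[nz])^2 - mu_alt[nz]) / sum(mu_alt[nz]^2)
    } else 0
    d <- max(d, 1e-8)
    size <- 1 / d
    lr <- 2 * (.nb_ll(y, mu_alt, size) - .nb_ll(y, mu_null, size))
    max(lr, 0)
  }

  scores <- apply(counts, 1L, score_one)
  mean_on <- rowMeans(cpm[, is_on, drop = FALSE])
  mean_off <- rowMeans(cpm[, !is_on, drop = FALSE])
  res <- data.frame(
    gene_id = rownames(counts),
    logFC = log2((mean_on + prior_cpm) / (mean_off + prior_cpm)),
    logCPM = log2(rowMeans(cpm) + prior_cpm),
    score = scores,
    p_value = stats::pchisq(scores, df = 1, lower.tail = FALSE),
    max_offsex_cpm = apply(cpm[, !is_on, drop = FALSE], 1L, max),
    min_onsex_cpm = apply(cpm[, is_on, drop = FALSE], 1L, min),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "on_group") <- on_lab
  attr(res, "off_group") <- off_lab
  res
}

#' Select a male-specific marker panel from scored genes
#'
#' From genes ranked by score, keeps those whose largest female (off-sex)
#' CPM is at most `max_offsex_cpm` and whose smallest male (on-sex) CPM is
#' at least `min_onsex_cpm`, and returns the top `top_k` survivors in rank
#' order as a marker panel. The rank alone is not enough: highly significant
#' genes can be female-enriched or expressed in both sexes, and only the
#' specificity filter excludes them.
#'
#' @param scores Data.frame from [nb_group_score()].
#' @param cfg A [discovery_config()].
#' @return A [marker_panel()] whose thresholds are taken from `cfg`.
#' @export
select_sex_markers <- function(scores, cfg = discovery_config()) {
  ok <- scores$max_offsex_cpm <= cfg$max_offsex_cpm &
        scores$min_onsex_cpm >= cfg$min_onsex_cpm
  survivors <- scores$gene_id[ok]
  if (length(survivors) < cfg$top_k) {
    warning("only ", length(survivors), " gene(s) pass the specificity ",
            "filter; panel smaller than top_k = ", cfg$top_k)
  }
  panel_genes <- utils::head(survivors, cfg$top_k)
  if (!length(panel_genes)) stop("no genes pass the specificity filter",
                                 call. = FALSE)
  marker_panel(panel_genes,
               tau_female = cfg$max_offsex_cpm,
               tau_male = cfg$min_onsex_cpm)
}

#' Run the full marker-discovery pipeline
#'
#' Window subset on chromosome Y, abundance filter, TMM/CPM, two-group NB
#' scoring, and male-specificity selection — in one call.
#'
#' @param counts Validated count matrix (genome-wide; library sizes and TMM
#'   factors are computed on all genes before subsetting).
#' @param annots Gene annotation data.frame.
#' @param groups Named male/female group vector.
#' @param cfg A [discovery_config()].
#' @param chrom Chromosome name carrying the search window.
#' @return List with `panel` (a [marker_panel()]), `scores` (all scored
#'   genes), and `norm_factors`.
#' @export
discover_markers <- function(counts, annots, groups, cfg = discovery_config(),
                             chrom = "Y") {
  counts <- validate_count_matrix(counts)
  factors <- tmm_norm_factors(counts)
  on_y <- annots[annots$chrom == chrom, , drop = FALSE]
  win <- subset_annotation_window(on_y, cfg$window_start, cfg$window_end)
  cand <- intersect(rownames(counts), win$gene_id)
  if (!length(cand)) stop("no count rows fall in the search window",
                          call. = FALSE)
  thr <- cfg$min_total_reads
  if (cfg$scale_min_reads_per_sample) thr <- thr / 64 * ncol(counts)
  sub <- filter_low_count_genes(counts[cand, , drop = FALSE], thr)
  if (!nrow(sub)) stop("no window genes pass the abundance filter",
                       call. = FALSE)
  # CPM on full-matrix library sizes and factors, as in the published
  # pipeline, then scoring restricted to the window genes
  scores <- nb_group_score_subset(counts, sub, groups, factors,
                                  prior_cpm = cfg$prior_cpm)
  panel <- select_sex_markers(scores, cfg)
  list(panel = panel, scores = scores, norm_factors = factors)
}

# Score only the rows of `sub` while taking library sizes (and hence CPM
# scale) from the full matrix `counts`.
nb_group_score_subset <- function(counts, sub, groups, norm_factors,
                                  prior_cpm = 0.25) {
  nb_group_score(sub, groups, norm_factors, prior_cpm,
                 lib_size = library_sizes(counts))
}

#' Marker panel constructor
#'
#' An ordered set of chromosome-Y marker genes with the two cumulative-CPM
#' decision thresholds used by [call_sex()]: at or below `tau_female` the
#' sample is called female, at or above `tau_male` male, in between
#' ambiguous.
#'
#' @param gene_ids Character vector of marker gene ids (ordered, nonempty).
#' @param tau_female,tau_male Cumulative-CPM thresholds, `tau_female <
#'   tau_male`.
#' @return A list of class `marker_panel`.
#' @export
marker_panel <- function(gene_ids, tau_female = 1.0, tau_male = 10.0) {
  stopifnot(length(gene_ids) >= 1L, !anyDuplicated(gene_ids),
            tau_female < tau_male, tau_female >= 0)
  structure(list(gene_ids = as.character(gene_ids),
                 tau_female = tau_female, tau_male = tau_male),
            class = "marker_panel")
}

#' The bundled bovine chromosome-Y marker panel
#'
#' The four-gene panel identified by the published tissue screen:
#' ENSBIXG00000029763, ENSBIXG00000029774, ENSBIXG00000029788 and
#' ENSBIXG00000029892, consistently expressed across male tissues and
#' absent or nearly absent in females.
#'
#' @return A [marker_panel()].
#' @export
bovine_chry_panel <- function() {
  default_assay()$panel
}

#' Write a discovery report table
#'
#' One row per scored gene, sorted by descending score, with panel genes
#' flagged; coordinates are attached when an annotation is supplied.
#'
#' @param scores Data.frame from [nb_group_score()].
#' @param panel A [marker_panel()].
#' @param path Output TSV path.
#' @param annots Optional annotation data.frame for coordinates/symbols.
#' @return The report data.frame, invisibly; written to `path` when given.
#' @export
discovery_report <- function(scores, panel, path = NULL, annots = NULL) {
  rep_ <- scores
  rep_$in_panel <- rep_$gene_id %in% panel$gene_ids
  if (!is.null(annots)) {
    idx <- match(rep_$gene_id, annots$gene_id)
    rep_$symbol <- annots$symbol[idx]
    rep_$chrom <- annots$chrom[idx]
    rep_$start <- annots$start[idx]
    rep_$end <- annots$end[idx]
  }
  num <- vapply(rep_, is.numeric, logical(1L))
  rep_[num] <- lapply(rep_[num], signif, digits = 6L)
  if (!is.null(path)) {
    utils::write.table(rep_, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rep_)
}
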