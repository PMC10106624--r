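#' Per-sample library sizes
#'
#' @param counts Validated count matrix.
#' @return Named numeric vector of column totals.
#' @export
library_sizes <- function(counts) {
  counts <- validate_count_matrix(counts)
  sizes <- colSums(counts)
  zero <- names(sizes)[sizes == 0]
  if (length(zero)) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  sizes
}

#' TMM normalization parameters
#'
#' Defaults mirror the documented defaults of the published trimmed mean of
#' M-values procedure: 30% two-sided trim on the log-ratios (M), 5% on the
#' average log-abundances (A), and inverse asymptotic-variance weighting of
#' the surviving M-values.
#'
#' @param logratio_trim Two-sided trim fraction applied to M-values.
#' @param abs_expr_trim Two-sided trim fraction applied to A-values.
#' @param weighted Weight M-values by inverse delta-method binomial variance.
#' @param ref_sample Optional sample id to use as the reference; when `NULL`
#'   the sample whose 75th-percentile count fraction is closest to the mean
#'   of those fractions is chosen.
#' @return A list of class `tmm_params`.
#' @export
tmm_params <- function(logratio_trim = 0.3, abs_expr_trim = 0.05,
                       weighted = TRUE, ref_sample = NULL) {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5)
  structure(list(logratio_trim = logratio_trim, abs_expr_trim = abs_expr_trim,
                 weighted = isTRUE(weighted), ref_sample = ref_sample),
            class = "tmm_params")
}

# One sample against the reference: weighted, doubly trimmed mean of
# log2 ratios on library-size-scaled counts. Genes with a zero count in
# either sample drop out pairwise before trimming.
.tmm_pair_factor <- function(obs, ref, n_obs, n_ref, params) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  if (!length(obs)) return(NA_real_)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # delta-method variance of M under binomial sampling of each library
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * params$logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * params$abs_expr_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(NA_real_)
  f <- if (params$weighted) {
    sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
  } else {
    mean(m[keep2])
  }
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample scaling factors from doubly trimmed,
#' variance-weighted log2 expression ratios against a reference sample,
#' implemented directly from the published TMM definition. The reference is
#' the sample whose 75th-percentile count fraction is closest to the mean of
#' those fractions (ties broken by input order). Factors are rescaled so
#' their geometric mean is 1.
#'
#' @param counts Validated count matrix with at least two samples.
#' @param params A [tmm_params()] object.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_norm_factors <- function(counts, params = tmm_params()) {
  counts <- validate_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  stopifnot(inherits(params, "tmm_params"))
  lib <- library_sizes(counts)
  if (is.null(params$ref_sample)) {
    f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
    if (all(f75 == 0)) stop("all 75th-percentile counts are zero", call. = FALSE)
    ref_idx <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_idx <- match(params$ref_sample, colnames(counts))
    if (is.na(ref_idx)) {
      stop("ref_sample not found: ", params$ref_sample, call. = FALSE)
    }
  }
  ref <- counts[, ref_idx]
  n_ref <- lib[ref_idx]
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair_factor(counts[, j], ref, lib[j], n_ref, params)
  }, numeric(1L))
  none <- is.na(factors)
  if (any(none)) {
    warning("no co-expressed genes with the reference for sample(s) ",
            paste(colnames(counts)[none], collapse = ", "),
            "; factor set to 1")
    factors[none] <- 1
  }
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  factors
}

#' Counts per million on effective library sizes
#'
#' `cpm(g, s) = count(g, s) / (library_size(s) * factor(s)) * 1e6`. No prior
#' count is added: the sexing decision rule depends on exact zeros in female
#' samples, which a pseudo-count would destroy.
#'
#' @param counts Validated count matrix.
#' @param norm_factors Named factor vector as from [tmm_norm_factors()];
#'   defaults to unit factors (plain CPM).
#' @return Numeric matrix of CPM values, same dimnames as `counts`.
#' @export
cpm_matrix <- function(counts, norm_factors = NULL) {
  counts <- validate_count_matrix(counts)
  lib <- library_sizes(counts)
  if (is.null(norm_factors)) {
    norm_factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  missing <- setdiff(colnames(counts), names(norm_factors))
  if (length(missing)) {
    stop("missing normalization factor for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(norm_factors <= 0)) stop("factors must be positive", call. = FALSE)
  eff <- lib * norm_factors[colnames(counts)]
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Write normalization factors as a two-column TSV
#' @param factors Named factor vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_factors <- function(factors, path) {
  utils::write.table(
    data.frame(sample_id = names(factors), norm_factor = unname(factors)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
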