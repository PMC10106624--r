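# Independent oracles, written as naive transliterations of the defining
# formulas. They deliberately share no code with the package internals.

# --- TMM: per-sample loop over genes, explicit trimming ----------------
naive_tmm <- function(counts, logratio_trim = 0.3, abs_expr_trim = 0.05,
                      weighted = TRUE, ref_sample = NULL) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f75[j] <- unname(stats::quantile(counts[, j], probs = 0.75)) / lib[j]
  }
  ref <- if (is.null(ref_sample)) which.min(abs(f75 - mean(f75)))
         else match(ref_sample, colnames(counts))
  out <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    m <- c(); a <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, j]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        po <- yo / lib[j]; pr <- yr / lib[ref]
        m <- c(m, log2(po / pr))
        a <- c(a, (log2(po) + log2(pr)) / 2)
        w <- c(w, (lib[j] - yo) / (lib[j] * yo) +
                 (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    if (length(m) == 0) { out[j] <- 1; next }
    if (max(abs(m)) < 1e-6) { out[j] <- 1; next }
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_expr_trim) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
            rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep)) { out[j] <- 1; next }
    f <- if (weighted) sum(m[keep] / w[keep]) / sum(1 / w[keep])
         else mean(m[keep])
    out[j] <- 2^f
  }
  out <- out / exp(mean(log(out)))
  names(out) <- colnames(counts)
  out
}

# Random small count matrix with NB structure, no all-zero samples.
random_count_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  mu <- rlnorm(n_genes, meanlog = 3, sdlog = 1.2)
  depth <- runif(n_samples, 0.5, 2)
  counts <- sapply(seq_len(n_samples), function(j) {
    rnbinom(n_genes, size = 5, mu = mu * depth[j])
  })
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- paste0("s", seq_len(n_samples))
  storage.mode(counts) <- "double"
  if (any(colSums(counts) == 0)) counts[1, ] <- counts[1, ] + 1
  counts
}

# --- primer matching: O(n*m) character scan ----------------------------
brute_revcomp <- function(seq_) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq_, "")[[1]]]), collapse = "")
}

brute_primer_scan <- function(template, primer, max_mismatch = 0,
                              anchor_3prime = 3) {
  tch <- strsplit(template, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else brute_revcomp(primer)
    pch <- strsplit(pat, "")[[1]]
    L <- length(pch)
    if (L > length(tch)) next
    for (s in seq_len(length(tch) - L + 1)) {
      win <- tch[s:(s + L - 1)]
      mm <- sum(win != pch) # N in the template never equals an ACGT base
      if (mm > max_mismatch) next
      if (anchor_3prime > 0) {
        anchor_idx <- if (strand == "+") (L - anchor_3prime + 1):L
                      else 1:anchor_3prime
        if (any(win[anchor_idx] != pch[anchor_idx])) next
      }
      rows[[length(rows) + 1]] <- data.frame(
        start = s, end = s + L - 1, strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a minimal Ensembl-dialect GTF for a data.frame of genes.
write_toy_gtf <- function(annots, path, with_transcripts = FALSE) {
  lines <- sprintf(
    '%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s";',
    annots$chrom, annots$start, annots$end, annots$gene_id,
    ifelse(is.na(annots$symbol), annots$gene_id, annots$symbol))
  if (with_transcripts) {
    tlines <- sprintf(
      paste0('%s\ttoy\ttranscript\t%d\t%d\t.\t+\t.\tgene_id "%s"; ',
             'transcript_id "%s.t1";'),
      annots$chrom, annots$start, annots$end, annots$gene_id,
      annots$gene_id)
    lines <- c(lines, tlines)
  }
  writeLines(lines, path)
  path
}
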