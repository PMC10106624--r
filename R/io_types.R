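#' Validate a count matrix
#'
#' A count matrix is a base integer-valued matrix of nonnegative read counts
#' with unique gene identifiers as rownames and unique sample identifiers as
#' colnames — the featureCounts/HTSeq-style table that drives everything
#' downstream.
#'
#' @param counts A numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @return The validated matrix, invisibly coerced to storage mode `double`
#'   (values are still whole numbers).
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  dup_g <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_g)) {
    stop("duplicate gene id: ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s)) {
    stop("duplicate sample id: ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integral", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a gene-by-sample count table
#'
#' Expects a tab-delimited file with a header row of sample ids, one row per
#' gene, and the gene id in the first column. Lines starting with `#` are
#' ignored (featureCounts writes a comment header).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, tab by default.
#' @return A validated count matrix (genes x samples).
#' @export
read_count_matrix <- function(path, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading id column name
  body <- fields[-1L]
  ncol_body <- lengths(body)
  n_samples <- if (length(header) == ncol_body[1L]) {
    length(header) - 1L
  } else {
    length(header)
  }
  sample_ids <- utils::tail(header, n_samples)
  bad <- which(ncol_body != n_samples + 1L)
  if (length(bad)) {
    stop("ragged row at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_samples))
  )
  if (anyNA(vals)) stop("non-numeric count entry in ", path, call. = FALSE)
  counts <- if (n_samples == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(counts) <- list(gene_ids, sample_ids)
  validate_count_matrix(counts)
}

#' Write a count table
#'
#' Inverse of [read_count_matrix()]: tab-delimited, `gene_id` first column,
#' sample ids as the remaining header fields. Whole-number values are written
#' without a decimal point so that read/write round-trips exactly.
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts),
                   format(counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge two count matrices counted against disjoint annotations
#'
#' Read counting is sometimes run independently against two annotations of
#' different chromosomes (e.g. the autosomal reference plus a separate
#' chromosome-Y annotation) to avoid merging GTF files; this stacks the two
#' resulting tables. Sample sets must be identical (order may differ; `b` is
#' realigned to `a`'s column order) and gene sets must be disjoint.
#'
#' @param a,b Validated count matrices over the same samples.
#' @return A single count matrix with `a`'s rows followed by `b`'s.
#' @export
merge_count_matrices <- function(a, b) {
  a <- validate_count_matrix(a)
  b <- validate_count_matrix(b)
  if (!setequal(colnames(a), colnames(b))) {
    stop("sample sets differ between the two matrices", call. = FALSE)
  }
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared)) {
    stop("overlapping gene ids: ", paste(utils::head(shared, 5L), collapse = ", "),
         call. = FALSE)
  }
  validate_count_matrix(rbind(a, b[, colnames(a), drop = FALSE]))
}

#' Read gene-level annotation from a GTF file
#'
#' Coordinates stay 1-based inclusive (the GTF convention). Only features of
#' type `gene` are returned; transcript and exon lines are ignored.
#'
#' @param path Path to an Ensembl-dialect GTF file.
#' @param chrom Optional chromosome name to restrict to.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `symbol` (NA when the GTF carries no `gene_name`).
#' @export
read_gene_annotation <- function(path, chrom = NULL) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf",
                                          feature.type = "gene"))
  ann <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(gr$seqnames),
    start = gr$start,
    end = gr$end,
    symbol = if (!is.null(gr$gene_name)) as.character(gr$gene_name)
             else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- is.na(ann$gene_id) | !nzchar(ann$gene_id)
  if (any(bad)) {
    warning(sum(bad), " gene feature(s) without a gene_id skipped")
    ann <- ann[!bad, , drop = FALSE]
  }
  if (!is.null(chrom)) ann <- ann[ann$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("zero gene features parsed from ", path,
         if (!is.null(chrom)) paste0(" on chromosome ", chrom), call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' Restrict annotation to a coordinate window
#'
#' By default a gene is retained only when fully contained in
#' `[win_start, win_end]` (both endpoints inclusive); `mode = "overlap"`
#' instead keeps any gene intersecting the window.
#'
#' @param annots Annotation data.frame as from [read_gene_annotation()].
#' @param win_start,win_end Window bounds, 1-based inclusive.
#' @param mode `"containment"` (default) or `"overlap"`.
#' @return The filtered annotation data.frame (possibly zero rows).
#' @export
subset_annotation_window <- function(annots, win_start, win_end,
                                     mode = c("containment", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(win_start <= win_end)
  keep <- if (mode == "containment") {
    annots$start >= win_start & annots$end <= win_end
  } else {
    annots$start <= win_end & annots$end >= win_start
  }
  out <- annots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are upper-cased and validated against the DNA alphabet: only
#' A, C, G, T and N are accepted (N is allowed in templates but never
#' matches a primer base downstream). RNA and other IUPAC ambiguity codes
#' are rejected rather than silently translated.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences; names are the first
#'   whitespace token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence record: ", ids[!nzchar(seqs)][1L], call. = FALSE)
  }
  has_bad <- vapply(regmatches(seqs, gregexpr("[^ACGTN]", seqs)),
                    function(x) length(x) > 0L, logical(1L))
  if (any(has_bad)) {
    ch <- regmatches(seqs[has_bad][1L], regexpr("[^ACGTN]", seqs[has_bad][1L]))
    stop("non-nucleotide character '", ch, "' in record ",
         ids[has_bad][1L], call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a sample-to-group mapping
#'
#' Two-column TSV (`sample_id`, `group`) with or without a header; groups are
#' free-form labels, typically `male` / `female` for discovery input.
#'
#' @param path TSV path.
#' @return Named character vector: names are sample ids, values group labels.
#' @export
read_sample_groups <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) stop("groups file needs two columns", call. = FALSE)
  groups <- as.character(df[[2L]])
  names(groups) <- as.character(df[[1L]])
  if (anyDuplicated(names(groups))) {
    stop("duplicate sample id in groups file", call. = FALSE)
  }
  groups
}

#' Check that a group mapping covers a count matrix
#' @param counts Count matrix.
#' @param groups Named group vector as from [read_sample_groups()].
#' @return `groups` restricted and reordered to `colnames(counts)`.
#' @export
align_sample_groups <- function(counts, groups) {
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups[colnames(counts)]
}
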