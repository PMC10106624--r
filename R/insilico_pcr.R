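#' Reverse complement of a DNA string
#' @param seq ACGTN string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Positions where a pattern occurs on one strand of the template with at
# most max_mismatch mismatches; N in the template counts as a mismatch
# against every primer base (fixed matching). Returns start, end, and
# per-hit mismatch counts on the + strand coordinate system.
.match_one_strand <- function(template_dna, pattern, max_mismatch) {
  hits <- Biostrings::matchPattern(pattern, template_dna,
                                   max.mismatch = max_mismatch,
                                   fixed = TRUE)
  # drop placements hanging off the template: a primer with missing ends
  # cannot delimit a product
  if (length(hits)) {
    inb <- IRanges::start(hits) >= 1L &
      IRanges::end(hits) <= length(template_dna)
    hits <- hits[inb]
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  pat_chars <- strsplit(pattern, "")[[1]]
  mm <- vapply(seq_along(hits), function(i) {
    sum(strsplit(as.character(hits[[i]]), "")[[1]] != pat_chars)
  }, integer(1L))
  data.frame(start = IRanges::start(hits), end = IRanges::end(hits),
             mismatches = mm)
}

#' Find primer annealing sites on both strands of a template
#'
#' A site is any placement of the primer, on either strand, with at most
#' `max_mismatch` mismatches whose 3'-terminal `anchor_3prime` bases match
#' exactly (polymerase extension needs a matched 3' end). `N` in the
#' template never matches a primer base. Coordinates are 1-based inclusive
#' on the forward strand of the template; a `-` strand site means the
#' primer anneals to the reverse strand, i.e. its reverse complement
#' appears in the template.
#'
#' @param template Template nucleotide string (ACGTN).
#' @param primer Primer, 5'->3' (ACGT).
#' @param max_mismatch Maximum mismatches tolerated outside the anchor.
#' @param anchor_3prime Number of 3'-terminal bases that must match exactly.
#' @param template_id Identifier copied into the result.
#' @return Data.frame with columns `template_id`, `start`, `end`, `strand`,
#'   `mismatches`. A primer longer than the template yields zero rows.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0,
                              anchor_3prime = 3, template_id = "template") {
  template <- toupper(template)
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer)) stop("primer must be ACGT", call. = FALSE)
  if (grepl("[^ACGTN]", template)) {
    stop("template must be ACGTN", call. = FALSE)
  }
  stopifnot(anchor_3prime >= 0, anchor_3prime <= nchar(primer))
  empty <- data.frame(template_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (nchar(primer) > nchar(template)) return(empty)
  tdna <- Biostrings::DNAString(template)
  plen <- nchar(primer)
  tchars <- strsplit(template, "")[[1]]
  pchars <- strsplit(primer, "")[[1]]

  fwd <- .match_one_strand(tdna, primer, max_mismatch)
  if (nrow(fwd)) {
    fwd$strand <- "+"
    # + strand: primer 3' end maps to the site's rightmost bases
    keep <- vapply(seq_len(nrow(fwd)), function(i) {
      if (anchor_3prime == 0L) return(TRUE)
      idx <- (fwd$end[i] - anchor_3prime + 1L):fwd$end[i]
      all(tchars[idx] == pchars[(plen - anchor_3prime + 1L):plen])
    }, logical(1L))
    fwd <- fwd[keep, , drop = FALSE]
  }
  rc <- revcomp(primer)
  rev <- .match_one_strand(tdna, rc, max_mismatch)
  if (nrow(rev)) {
    rev$strand <- "-"
    # - strand: primer 3' end maps to the site's leftmost bases (revcomp)
    rc_chars <- strsplit(rc, "")[[1]]
    keep <- vapply(seq_len(nrow(rev)), function(i) {
      if (anchor_3prime == 0L) return(TRUE)
      idx <- rev$start[i]:(rev$start[i] + anchor_3prime - 1L)
      all(tchars[idx] == rc_chars[seq_len(anchor_3prime)])
    }, logical(1L))
    rev <- rev[keep, , drop = FALSE]
  }
  out <- rbind(fwd, rev)
  if (!nrow(out)) return(empty)
  out <- data.frame(template_id = template_id, out,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Enumerate PCR products of a primer pair on a template
#'
#' A product is delimited by a forward-oriented site of one primer and a
#' downstream reverse-oriented site of the other (either primer can play
#' either part, so both template orientations are covered). Product length
#' includes both primers: `length = end - start + 1` with `start`/`end` the
#' outermost primer bases, 1-based inclusive.
#'
#' @param template Template nucleotide string.
#' @param pair A [primer_pair()].
#' @param max_len Maximum product length in bp (default 5000; beyond any
#'   plausible short-extension gel band).
#' @param max_mismatch,anchor_3prime Matching stringency, as in
#'   [find_primer_sites()].
#' @param template_id Identifier copied into the result.
#' @return Data.frame with columns `template_id`, `pair_name`, `start`,
#'   `end`, `length`, `total_mismatches`, `length_within_expected`
#'   (NA when the pair declares no expected length; tolerance 10%,
#'   reporting only).
#' @export
enumerate_amplicons <- function(template, pair, max_len = 5000,
                                max_mismatch = 0, anchor_3prime = 3,
                                template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  f_sites <- find_primer_sites(template, pair$forward, max_mismatch,
                               anchor_3prime, template_id)
  r_sites <- find_primer_sites(template, pair$reverse, max_mismatch,
                               anchor_3prime, template_id)
  min_len <- nchar(pair$forward) + nchar(pair$reverse)
  combos <- rbind(
    merge(f_sites[f_sites$strand == "+", c("start", "end", "mismatches")],
          r_sites[r_sites$strand == "-", c("start", "end", "mismatches")],
          by = NULL, suffixes = c("_l", "_r")),
    merge(r_sites[r_sites$strand == "+", c("start", "end", "mismatches")],
          f_sites[f_sites$strand == "-", c("start", "end", "mismatches")],
          by = NULL, suffixes = c("_l", "_r"))
  )
  if (!nrow(combos)) {
    return(data.frame(template_id = character(), pair_name = character(),
                      start = integer(), end = integer(), length = integer(),
                      total_mismatches = integer(),
                      length_within_expected = logical(),
                      stringsAsFactors = FALSE))
  }
  combos$length <- combos$end_r - combos$start_l + 1L
  ok <- combos$length >= min_len & combos$length <= max_len
  combos <- combos[ok, , drop = FALSE]
  out <- data.frame(template_id = template_id, pair_name = pair$name,
                    start = combos$start_l, end = combos$end_r,
                    length = combos$length,
                    total_mismatches = combos$mismatches_l +
                      combos$mismatches_r,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out$length_within_expected <- if (is.null(pair$expected_length)) {
    NA
  } else {
    abs(out$length - pair$expected_length) <= 0.1 * pair$expected_length
  }
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a multiplex PCR reaction on one template
#'
#' Runs every primer pair of the assay against the template and interprets
#' the band pattern: at least one male-specific band plus at least one
#' control band reads male; control band(s) only reads female; no control
#' band means the reaction failed (indeterminate), never female.
#'
#' @param template Template nucleotide string (a genome or genome segment).
#' @param assay An [assay_definition()].
#' @param max_len,max_mismatch,anchor_3prime As in [enumerate_amplicons()].
#' @param template_id Identifier copied into the result.
#' @return A list of class `multiplex_result`: `template_id`, `bands`
#'   (amplicon data.frame across pairs), `call` in
#'   `{"male", "female", "indeterminate"}`.
#' @export
simulate_multiplex <- function(template, assay, max_len = 5000,
                               max_mismatch = 0, anchor_3prime = 3,
                               template_id = "template") {
  stopifnot(inherits(assay, "assay_definition"))
  bands <- do.call(rbind, lapply(assay$primer_pairs, function(p) {
    enumerate_amplicons(template, p, max_len, max_mismatch, anchor_3prime,
                        template_id)
  }))
  rownames(bands) <- NULL
  roles <- vapply(assay$primer_pairs, `[[`, character(1L), "role")
  male_pairs <- names(assay$primer_pairs)[roles == "male_specific"]
  ctrl_pairs <- names(assay$primer_pairs)[roles == "control"]
  has_male <- any(bands$pair_name %in% male_pairs)
  has_ctrl <- any(bands$pair_name %in% ctrl_pairs)
  call <- if (!has_ctrl) "indeterminate" else if (has_male) "male" else "female"
  structure(list(template_id = template_id, bands = bands, call = call),
            class = "multiplex_result")
}

#' @export
print.multiplex_result <- function(x, ...) {
  cat("Multiplex PCR on", x$template_id, "->", x$call, "\n")
  if (nrow(x$bands)) {
    print(x$bands, row.names = FALSE)
  } else {
    cat("(no bands)\n")
  }
  invisible(x)
}

#' Align an amplicon to a reference to verify its identity
#'
#' Best local alignment (match +1, mismatch -1, gap -2 per gapped base)
#' of the amplicon sequence on the reference, mirroring the wet-lab
#' validation step of aligning a Sanger-sequenced product back to the
#' chromosome-Y assembly.
#'
#' @param amplicon_sequence Query nucleotide string.
#' @param reference Reference nucleotide string.
#' @return List with `identity_pct` (percent identity over aligned
#'   columns), `ref_start`, `ref_end` (1-based inclusive placement), and
#'   `alignment_score`.
#' @export
verify_amplicon_identity <- function(amplicon_sequence, reference) {
  if (!nzchar(amplicon_sequence) || !nzchar(reference)) {
    stop("empty sequence", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(amplicon_sequence)),
    subject = Biostrings::DNAString(toupper(reference)),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  list(identity_pct = Biostrings::pid(aln, type = "PID1"),
       ref_start = IRanges::start(Biostrings::subject(aln)),
       ref_end = IRanges::end(Biostrings::subject(aln)),
       alignment_score = BiocGenerics::score(aln))
}

#' Check the published amplicon-length claims against real sequences
#'
#' Runs the bundled assay's primer pairs against user-supplied genome
#' sequences and compares each empirical product length with the pair's
#' declared expected length, reporting — never reconciling — any
#' discrepancy. Intended for the chromosome-Y assembly (CM011803.1) and
#' reference chromosome 28, which are too large to bundle; supply FASTA
#' paths after downloading them.
#'
#' @param fasta_paths Named character vector of FASTA paths; names are
#'   labels for the report.
#' @param assay An [assay_definition()] (default: bundled bovine assay).
#' @param max_mismatch Matching stringency.
#' @return Data.frame with one row per (template, pair, product):
#'   empirical `start`, `end`, `length`, the pair's `expected_length`, and
#'   `matches_expected`.
#' @export
verify_published_amplicons <- function(fasta_paths, assay = default_assay(),
                                       max_mismatch = 0) {
  rows <- list()
  for (lab in names(fasta_paths)) {
    seqs <- read_fasta(fasta_paths[[lab]])
    for (sid in names(seqs)) {
      for (p in assay$primer_pairs) {
        amp <- enumerate_amplicons(seqs[[sid]], p,
                                   max_mismatch = max_mismatch,
                                   template_id = paste(lab, sid))
        if (nrow(amp)) {
          amp$expected_length <- if (is.null(p$expected_length)) NA_integer_
                                 else p$expected_length
          amp$matches_expected <- amp$length == amp$expected_length
          rows[[length(rows) + 1L]] <- amp
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(template_id = character(), pair_name = character(),
               start = integer(), end = integer(), length = integer(),
               total_mismatches = integer(),
               length_within_expected = logical(),
               expected_length = integer(), matches_expected = logical())
  rownames(out) <- NULL
  mismatched <- out[!is.na(out$matches_expected) & !out$matches_expected, ]
  if (nrow(mismatched)) {
    warning("empirical amplicon length differs from the declared expected ",
            "length for: ",
            paste(sprintf("%s (%d vs %d)", mismatched$pair_name,
                          mismatched$length, mismatched$expected_length),
                  collapse = ", "))
  }
  out
}
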