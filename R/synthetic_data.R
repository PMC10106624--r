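#' Parameterization of a synthetic sexing dataset
#'
#' Defines the ground-truth simulation the test-bed runs on: a
#' negative-binomial count matrix with planted male-exclusive chromosome-Y
#' marker genes over a background of sex-neutral genes. Defaults emulate
#' the study conditions of a low-input bovine RNA-seq cohort: ten samples
#' per sex, library sizes log-uniform over 10-40 million fragments (the
#' reported per-sex average depths), four planted markers at 40 CPM each in
#' males (cumulative approximately 160, near the reported male blastocyst
#' average of 161.38), females exactly zero except rare leaks
#' (probability 0.05 per marker-sample cell) at 0.05 CPM, mirroring the one
#' observed 0.0592 CPM female value, and NB dispersion 0.1 (typical bulk
#' RNA-seq).
#'
#' @param n_male,n_female Samples per sex.
#' @param n_background_genes Sex-neutral genes (placed on autosomes).
#' @param n_marker_genes Planted male-exclusive chromosome-Y genes.
#' @param lib_size_range Two-element range; library sizes are drawn
#'   log-uniformly over it.
#' @param marker_male_cpm_mean Target per-marker CPM in male samples.
#' @param female_leak_prob Probability a female marker cell leaks at all.
#' @param female_leak_cpm CPM scale of a leak when it occurs.
#' @param dispersion NB dispersion d (variance = mu + d * mu^2).
#' @param seed Integer seed; every output is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_male = 10, n_female = 10,
                           n_background_genes = 996, n_marker_genes = 4,
                           lib_size_range = c(1e7, 4e7),
                           marker_male_cpm_mean = 40,
                           female_leak_prob = 0.05, female_leak_cpm = 0.05,
                           dispersion = 0.1, seed = 1L) {
  stopifnot(n_male >= 1, n_female >= 1, n_background_genes >= 1,
            n_marker_genes >= 1, length(lib_size_range) == 2L,
            all(lib_size_range > 0),
            lib_size_range[1] <= lib_size_range[2],
            marker_male_cpm_mean > 0,
            female_leak_prob >= 0, female_leak_prob <= 1,
            female_leak_cpm >= 0, dispersion >= 0)
  if (marker_male_cpm_mean >= 1e6) {
    stop("marker_male_cpm_mean exceeds the library-size scale (1e6 CPM)",
         call. = FALSE)
  }
  structure(list(n_male = n_male, n_female = n_female,
                 n_background_genes = n_background_genes,
                 n_marker_genes = n_marker_genes,
                 lib_size_range = lib_size_range,
                 marker_male_cpm_mean = marker_male_cpm_mean,
                 female_leak_prob = female_leak_prob,
                 female_leak_cpm = female_leak_cpm,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# rnbinom with dispersion d: size = 1/d; d = 0 degenerates to Poisson.
.rnb <- function(n, mu, d) {
  if (d <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / d, mu = mu)
}

#' Simulate a ground-truth count dataset
#'
#' Background genes share one mean-CPM profile across sexes (log-normal
#' across genes, rescaled to fill the library); marker genes are NB at the
#' target male CPM in males and exactly zero in females except Bernoulli
#' leaks of one or a few reads. Marker genes are annotated inside the
#' chromosome-Y search window; background genes go on autosomes.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (count matrix), `annots` (annotation
#'   data.frame), `groups` (named sex vector), `truth` (list: `sexes`,
#'   `marker_genes`, `lib_sizes`, `marker_male_cpm_mean`).
#' @export
simulate_counts <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n_s <- spec$n_male + spec$n_female
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  names(sexes) <- sample_ids

  lib <- exp(stats::runif(n_s, log(spec$lib_size_range[1]),
                          log(spec$lib_size_range[2])))

  n_bg <- spec$n_background_genes
  n_mk <- spec$n_marker_genes
  bg_ids <- sprintf("BG%04d", seq_len(n_bg))
  mk_ids <- sprintf("CHRY_MARKER%02d", seq_len(n_mk))

  # background relative abundances: log-normal across genes, rescaled so
  # the expected library is filled by background expression
  rel <- stats::rlnorm(n_bg, meanlog = 0, sdlog = 1.5)
  bg_cpm <- rel / sum(rel) * 1e6

  counts <- matrix(0, nrow = n_bg + n_mk, ncol = n_s,
                   dimnames = list(c(bg_ids, mk_ids), sample_ids))
  for (j in seq_len(n_s)) {
    counts[bg_ids, j] <- .rnb(n_bg, bg_cpm * lib[j] / 1e6, spec$dispersion)
  }
  is_male <- sexes == "male"
  for (j in which(is_male)) {
    mu <- spec$marker_male_cpm_mean * lib[j] / 1e6
    counts[mk_ids, j] <- .rnb(n_mk, mu, spec$dispersion)
  }
  for (j in which(!is_male)) {
    leak <- stats::runif(n_mk) < spec$female_leak_prob
    if (any(leak)) {
      mu <- spec$female_leak_cpm * lib[j] / 1e6
      counts[mk_ids[leak], j] <- pmax(1, stats::rpois(sum(leak), mu))
    }
  }

  # annotation: markers inside the chromosome-Y search window, background
  # genes spread over the autosomes
  mk_start <- as.integer(seq(6960000, 15000000, length.out = n_mk))
  annots <- rbind(
    data.frame(gene_id = bg_ids,
               chrom = as.character(rep_len(1:29, n_bg)),
               start = as.integer(seq(1e5, 5e7, length.out = n_bg)),
               end = as.integer(seq(1e5, 5e7, length.out = n_bg)) + 5000L,
               symbol = NA_character_, stringsAsFactors = FALSE),
    data.frame(gene_id = mk_ids, chrom = "Y",
               start = mk_start, end = mk_start + 20000L,
               symbol = NA_character_, stringsAsFactors = FALSE)
  )

  list(counts = validate_count_matrix(counts),
       annots = annots,
       groups = sexes,
       truth = list(sexes = sexes, marker_genes = mk_ids,
                    lib_sizes = stats::setNames(lib, sample_ids),
                    marker_male_cpm_mean = spec$marker_male_cpm_mean))
}

# Save/restore the global RNG state so simulation calls are reproducible
# from their own seed without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a male and a female genome carrying planted primer sites
#'
#' The female sequence carries one planted product construct for every
#' control pair (forward primer + spacer + reverse complement of the
#' reverse primer, spacer sized so the product has the pair's expected
#' length); the male sequence additionally carries the male-specific
#' pair's construct. Placements are random but seed-reproducible and
#' non-overlapping, and the background is redrawn (bounded retries) until
#' a brute-force scan finds each primer site exactly once and no
#' accidental extras.
#'
#' @param seed Integer seed.
#' @param genome_len Total length of each simulated genome in bp.
#' @param assay An [assay_definition()].
#' @param max_tries Redraw attempts before giving up.
#' @return List with `male` and `female` (named character vectors of
#'   length 1, names `syn_male` / `syn_female`).
#' @export
simulate_genome_pair <- function(seed = 1L, genome_len = 20000,
                                 assay = default_assay(), max_tries = 20L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pairs <- assay$primer_pairs
  roles <- vapply(pairs, `[[`, character(1L), "role")

  construct <- function(p) {
    prod_len <- if (!is.null(p$expected_length)) p$expected_length
                else nchar(p$forward) + nchar(p$reverse) + 100L
    spacer <- prod_len - nchar(p$forward) - nchar(p$reverse)
    stopifnot(spacer >= 0)
    paste0(p$forward, .random_dna(spacer), revcomp(p$reverse))
  }

  plant <- function(genome, inserts) {
    # carve non-overlapping slots for the inserts
    lens <- nchar(inserts)
    stopifnot(sum(lens) < nchar(genome))
    n <- length(inserts)
    gap <- (nchar(genome) - sum(lens)) %/% (n + 1L)
    pos <- cumsum(c(gap, utils::head(lens + gap, n - 1L)))
    jitter <- sample.int(max(gap %/% 2L, 1L), n) - 1L
    pos <- pos + jitter
    out <- genome
    for (i in seq_len(n)) {
      substr(out, pos[i] + 1L, pos[i] + lens[i]) <- inserts[i]
    }
    out
  }

  clean <- function(seq_, expected_sites) {
    # every assay primer must occur exactly its expected number of times
    for (p in pairs) {
      for (primer in c(p$forward, p$reverse)) {
        hits <- find_primer_sites(seq_, primer, max_mismatch = 0,
                                  anchor_3prime = 0)
        if (nrow(hits) != expected_sites[[p$name]]) return(FALSE)
      }
    }
    TRUE
  }

  draw <- function(which_pairs) {
    expected <- stats::setNames(
      as.list(as.integer(names(pairs) %in% which_pairs)), names(pairs))
    for (try_ in seq_len(max_tries)) {
      genome <- .random_dna(genome_len)
      inserts <- vapply(pairs[which_pairs], construct, character(1L))
      g <- plant(genome, inserts)
      if (clean(g, expected)) return(g)
    }
    stop("could not place primer sites without collisions after ",
         max_tries, " tries", call. = FALSE)
  }

  ctrl <- names(pairs)[roles == "control"]
  male_set <- names(pairs)
  female <- draw(ctrl)
  male <- draw(male_set)
  list(male = stats::setNames(male, "syn_male"),
       female = stats::setNames(female, "syn_female"))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits `counts.tsv`, `annotation.gtf`, `groups.tsv`, `male.fa`,
#' `female.fa` and `truth.json` for one spec/seed, all re-readable by the
#' package's own readers.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()]; its seed also seeds the genome pair.
#' @param assay An [assay_definition()].
#' @return Named character vector of the six file paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, spec = synthetic_spec(),
                                 assay = default_assay()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(spec)
  genomes <- simulate_genome_pair(seed = spec$seed, assay = assay)

  paths <- c(counts = file.path(dir, "counts.tsv"),
             annotation = file.path(dir, "annotation.gtf"),
             groups = file.path(dir, "groups.tsv"),
             male_fa = file.path(dir, "male.fa"),
             female_fa = file.path(dir, "female.fa"),
             truth = file.path(dir, "truth.json"))

  write_count_matrix(sim$counts, paths[["counts"]])
  writeLines(with(sim$annots, sprintf(
    paste0('%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\t',
           'gene_id "%s"; gene_biotype "protein_coding";'),
    chrom, start, end, gene_id)), paths[["annotation"]])
  utils::write.table(
    data.frame(sample_id = names(sim$groups), group = unname(sim$groups)),
    paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_fasta(genomes$male, paths[["male_fa"]])
  write_fasta(genomes$female, paths[["female_fa"]])
  jsonlite::write_json(
    list(sexes = as.list(sim$truth$sexes),
         marker_genes = sim$truth$marker_genes,
         lib_sizes = as.list(round(sim$truth$lib_sizes, 3)),
         marker_male_cpm_mean = sim$truth$marker_male_cpm_mean,
         seed = spec$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
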