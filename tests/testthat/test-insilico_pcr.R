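msy_pair <- function() default_assay()$primer_pairs[["MSY"]]

test_that("exact primer occurrences are found on both strands", {
  p <- msy_pair()
  left <- random_dna_str(50, seed = 1)
  right <- random_dna_str(60, seed = 2)
  tpl <- paste0(left, p$forward, right)
  sites <- find_primer_sites(tpl, p$forward)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 51L)
  expect_equal(sites$end, 50L + nchar(p$forward))
  expect_equal(sites$mismatches, 0L)

  tpl_rc <- paste0(left, revcomp(p$forward), right)
  sites_rc <- find_primer_sites(tpl_rc, p$forward)
  expect_equal(nrow(sites_rc), 1L)
  expect_equal(sites_rc$strand, "-")

  # primer longer than template: empty, not an error
  expect_equal(nrow(find_primer_sites("ACGT", p$forward)), 0L)
})

test_that("mismatch tolerance respects the 3' anchor and N never matches", {
  set.seed(33)
  primer <- random_dna_str(20)
  flip <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  bg <- random_dna_str(10000)

  # internal mismatch (position 5): found with max_mismatch 1
  ch <- strsplit(primer, "")[[1]]
  ch[5] <- flip(ch[5])
  tpl <- paste0(substr(bg, 1, 4000), paste(ch, collapse = ""),
                substr(bg, 4001, 10000))
  hit <- find_primer_sites(tpl, primer, max_mismatch = 1, anchor_3prime = 3)
  expect_true(any(hit$start == 4001 & hit$mismatches == 1))
  expect_equal(nrow(find_primer_sites(tpl, primer, max_mismatch = 0)), 0L)

  # 3'-terminal mismatch: rejected even with max_mismatch 1
  ch2 <- strsplit(primer, "")[[1]]
  ch2[20] <- flip(ch2[20])
  tpl2 <- paste0(substr(bg, 1, 4000), paste(ch2, collapse = ""),
                 substr(bg, 4001, 10000))
  hit2 <- find_primer_sites(tpl2, primer, max_mismatch = 1,
                            anchor_3prime = 3)
  expect_false(any(hit2$start == 4001))

  # N in the template counts as a mismatch
  chN <- strsplit(primer, "")[[1]]
  chN[5] <- "N"
  tplN <- paste0("ACGT", paste(chN, collapse = ""), "ACGT")
  expect_equal(nrow(find_primer_sites(tplN, primer, max_mismatch = 0)), 0L)
  hitN <- find_primer_sites(tplN, primer, max_mismatch = 1)
  expect_equal(hitN$mismatches, 1L)
})

test_that("site search matches the brute-force scanner on random instances", {
  n_match <- 0
  for (i in 1:100) {
    set.seed(5000 + i)
    tpl <- random_dna_str(300)
    # half the time plant a perturbed primer to make hits likely
    primer <- random_dna_str(sample(8:14, 1))
    if (i %% 2 == 0) {
      pos <- sample(280, 1)
      substr(tpl, pos, pos + nchar(primer) - 1) <- primer
    }
    mm <- sample(0:2, 1)
    anch <- sample(0:3, 1)
    got <- find_primer_sites(tpl, primer, max_mismatch = mm,
                             anchor_3prime = anch)
    want <- brute_primer_scan(tpl, primer, max_mismatch = mm,
                              anchor_3prime = anch)
    expect_equal(got[, c("start", "end", "strand", "mismatches")],
                 want, ignore_attr = TRUE)
    n_match <- n_match + 1
  }
  expect_equal(n_match, 100)
})

test_that("amplicon lengths follow the planted-construct convention", {
  p <- primer_pair("toy", "AGGGTGAAGCAAATGGTCGT", "GGAGCAACAGTGTCCTGTGT",
                   role = "control")
  set.seed(12)
  spacer <- random_dna_str(100)
  tpl <- paste0(random_dna_str(30), p$forward, spacer, revcomp(p$reverse),
                random_dna_str(30))
  amp <- enumerate_amplicons(tpl, p)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 20L + 100L + 20L)
  expect_equal(amp$start, 31L)
  expect_equal(amp$end, 30L + 140L)

  # no reverse site -> no product
  tpl2 <- paste0(random_dna_str(30), p$forward, spacer)
  expect_equal(nrow(enumerate_amplicons(tpl2, p)), 0L)

  # two reverse sites downstream -> two products with predictable lengths
  tpl3 <- paste0(random_dna_str(30), p$forward, spacer,
                 revcomp(p$reverse), random_dna_str(50),
                 revcomp(p$reverse), random_dna_str(20))
  amp3 <- enumerate_amplicons(tpl3, p)
  expect_equal(sort(amp3$length), c(140L, 140L + 50L + 20L))

  # a product longer than max_len is suppressed
  amp_cap <- enumerate_amplicons(tpl3, p, max_len = 150)
  expect_equal(amp_cap$length, 140L)
})

test_that("amplicon length multiset is reverse-complement symmetric", {
  assay <- default_assay()
  for (seed in 1:5) {
    g <- simulate_genome_pair(seed = seed, assay = assay)
    for (tpl in c(g$male[[1]], g$female[[1]])) {
      for (p in assay$primer_pairs) {
        a1 <- enumerate_amplicons(tpl, p)
        a2 <- enumerate_amplicons(revcomp(tpl), p)
        expect_equal(sort(a1$length), sort(a2$length))
      }
    }
  }
})

test_that("multiplex band patterns translate to sex calls", {
  assay <- default_assay()
  g <- simulate_genome_pair(seed = 101, assay = assay)
  male <- simulate_multiplex(g$male[[1]], assay, template_id = "syn_male")
  female <- simulate_multiplex(g$female[[1]], assay,
                               template_id = "syn_female")
  expect_equal(male$call, "male")
  expect_equal(nrow(male$bands), 2L)
  expect_setequal(male$bands$pair_name, c("MSY", "CDK1"))
  expect_equal(female$call, "female")
  expect_equal(female$bands$pair_name, "CDK1")

  # a template with no sites at all is a failed reaction, not a female
  blank <- simulate_multiplex(random_dna_str(2000, seed = 3), assay)
  expect_equal(blank$call, "indeterminate")

  # male-specific band without a control band is also indeterminate
  p <- assay$primer_pairs[["MSY"]]
  msy_only <- paste0(random_dna_str(100, seed = 4), p$forward,
                     random_dna_str(200), revcomp(p$reverse),
                     random_dna_str(100))
  expect_equal(simulate_multiplex(msy_only, assay)$call, "indeterminate")
})

test_that("amplicon identity verification scores local alignments", {
  set.seed(77)
  ref <- random_dna_str(10000)
  amp <- substr(ref, 2001, 2100)
  res <- verify_amplicon_identity(amp, ref)
  expect_equal(res$identity_pct, 100)
  expect_equal(res$ref_start, 2001)
  expect_equal(res$ref_end, 2100)

  # one internal substitution over 100 bp -> 99% identity
  mut <- amp
  old <- substr(mut, 50, 50)
  substr(mut, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  res2 <- verify_amplicon_identity(mut, ref)
  expect_equal(res2$identity_pct, 99)

  # unrelated query aligns poorly
  res3 <- verify_amplicon_identity(random_dna_str(100), ref)
  expect_lt(res3$identity_pct, 80)

  expect_error(verify_amplicon_identity("", ref), "empty sequence")
})

test_that("declared expected lengths are checked, not enforced", {
  # plant a 287 nt product while declaring 279: the discrepancy must be
  # reported and the empirical length returned unchanged
  p <- primer_pair("claim", "AGGGTGAAGCAAATGGTCGT", "GGAGCAACAGTGTCCTGTGT",
                   role = "male_specific", expected_length = 279)
  set.seed(8)
  tpl <- paste0(random_dna_str(40), p$forward, random_dna_str(287 - 40),
                revcomp(p$reverse), random_dna_str(40))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(syn_claim_template = tpl), fa)
  ctrl <- default_assay()$primer_pairs[["CDK1"]]
  assay <- assay_definition(marker_panel("x"), list(p, ctrl))
  expect_warning(
    rep_ <- verify_published_amplicons(c(syn = fa), assay),
    "differs from the declared")
  expect_equal(rep_$length, 287L)
  expect_equal(rep_$expected_length, 279L)
  expect_false(rep_$matches_expected)
})
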