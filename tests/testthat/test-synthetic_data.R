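test_that("count simulation is deterministic and respects the leak model", {
  s1 <- simulate_counts(synthetic_spec(seed = 4))
  s2 <- simulate_counts(synthetic_spec(seed = 4))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$lib_sizes, s2$truth$lib_sizes)
  s3 <- simulate_counts(synthetic_spec(seed = 5))
  expect_false(identical(s1$counts, s3$counts))

  # zero leak probability: every female marker count is exactly 0
  nl <- simulate_counts(synthetic_spec(female_leak_prob = 0, seed = 6))
  females <- names(nl$groups)[nl$groups == "female"]
  expect_true(all(nl$counts[nl$truth$marker_genes, females] == 0))

  # markers annotated on Y inside the search window, background elsewhere
  ann <- s1$annots
  mk <- ann[ann$gene_id %in% s1$truth$marker_genes, ]
  expect_true(all(mk$chrom == "Y"))
  expect_true(all(mk$start >= 6953027 & mk$end <= 15591347))
  expect_true(all(ann$chrom[!ann$gene_id %in% mk$gene_id] != "Y"))
})

test_that("simulated marker abundance hits its CPM target on average", {
  target <- 40
  means <- vapply(1:20, function(seed) {
    sim <- simulate_counts(synthetic_spec(seed = seed))
    cpm <- cpm_matrix(sim$counts)
    males <- names(sim$groups)[sim$groups == "male"]
    mean(cpm[sim$truth$marker_genes, males])
  }, numeric(1))
  expect_lt(abs(mean(means) - target) / target, 0.25)
})

test_that("marker separation between sexes spans orders of magnitude", {
  sim <- simulate_counts(synthetic_spec(seed = 13))
  cpm <- cpm_matrix(sim$counts, tmm_norm_factors(sim$counts))
  cum <- cumulative_marker_cpm(cpm, marker_panel(sim$truth$marker_genes))
  males <- names(sim$groups)[sim$groups == "male"]
  females <- names(sim$groups)[sim$groups == "female"]
  expect_gt(mean(cum[males]) / max(mean(cum[females]), 1e-2), 100)
})

test_that("genome pair simulation plants each primer site exactly once", {
  assay <- default_assay()
  for (seed in 1:10) {
    g <- simulate_genome_pair(seed = seed, assay = assay)
    for (p in assay$primer_pairs) {
      male_f <- find_primer_sites(g$male[[1]], p$forward, 0, 0)
      male_r <- find_primer_sites(g$male[[1]], p$reverse, 0, 0)
      expect_equal(nrow(male_f), 1L)
      expect_equal(nrow(male_r), 1L)
      n_expected <- as.integer(p$role == "control")
      expect_equal(nrow(find_primer_sites(g$female[[1]], p$forward, 0, 0)),
                   n_expected)
    }
  }
  # same seed, same genomes
  expect_identical(simulate_genome_pair(seed = 3),
                   simulate_genome_pair(seed = 3))
})

test_that("fixture bundles are complete, re-readable, and deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 9)
  p1 <- write_fixture_bundle(dir1, spec)
  p2 <- write_fixture_bundle(dir2, spec)
  expect_length(p1, 6L)
  expect_true(all(file.exists(p1)))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("bundle file", k))
  }

  counts <- read_count_matrix(p1[["counts"]])
  sim <- simulate_counts(spec)
  expect_equal(counts, sim$counts)
  ann <- read_gene_annotation(p1[["annotation"]])
  expect_setequal(ann$gene_id, rownames(counts))
  groups <- read_sample_groups(p1[["groups"]])
  expect_equal(align_sample_groups(counts, groups), sim$groups)
  truth <- jsonlite::read_json(p1[["truth"]])
  expect_equal(unlist(truth$marker_genes), sim$truth$marker_genes)

  male <- read_fasta(p1[["male_fa"]])
  expect_equal(names(male), "syn_male")
})

test_that("infeasible specs are rejected up front", {
  expect_error(synthetic_spec(marker_male_cpm_mean = 2e6),
               "library-size scale")
  expect_error(synthetic_spec(female_leak_prob = 1.5))
  expect_error(synthetic_spec(lib_size_range = c(10, 5)))
})
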