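make_two_group <- function(counts_on, counts_off) {
  m <- cbind(counts_on, counts_off)
  colnames(m) <- c(paste0("m", seq_len(ncol(counts_on))),
                   paste0("f", seq_len(ncol(counts_off))))
  groups <- c(rep("male", ncol(counts_on)), rep("female", ncol(counts_off)))
  names(groups) <- colnames(m)
  list(counts = m, groups = groups)
}

test_that("abundance filter applies a strict inequality on raw totals", {
  totals <- c(0, 100, 600, 601, 1000, 5000)
  m <- cbind(floor(totals / 2), ceiling(totals / 2))
  dimnames(m) <- list(paste0("g", 1:6), c("s1", "s2"))
  kept <- filter_low_count_genes(m, 600)
  expect_equal(rownames(kept), c("g4", "g5", "g6"))
  # 601 kept, exactly 600 dropped
  expect_true("g4" %in% rownames(kept))
  expect_false("g3" %in% rownames(kept))
})

test_that("NB scoring: null genes score ~0, separated genes top the list", {
  set.seed(1)
  base <- matrix(rnbinom(50 * 8, size = 10, mu = 100), nrow = 50)
  rownames(base) <- paste0("g", 1:50)
  # a gene identical in every sample
  base["g1", ] <- 100
  # a male-exclusive gene
  base["g2", 1:4] <- c(900, 1100, 1000, 950)
  base["g2", 5:8] <- 0
  tg <- make_two_group(base[, 1:4], base[, 5:8])
  # equalize library sizes so the identical-counts gene is an exact null
  sc <- nb_group_score(tg$counts, tg$groups,
                       lib_size = setNames(rep(1e4, 8), colnames(tg$counts)))
  g1 <- sc[sc$gene_id == "g1", ]
  expect_equal(g1$logFC, 0, tolerance = 1e-12)
  expect_lt(g1$score, 1e-6)
  expect_equal(sc$gene_id[1], "g2")
  expect_gt(sc[1, "logFC"], 0)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  expect_true(all(sc$score >= 0))
})

test_that("NB scoring is label-symmetric and order-invariant", {
  m <- random_count_matrix(80, 8, seed = 5)
  groups <- setNames(rep(c("male", "female"), each = 4), colnames(m))
  sc <- nb_group_score(m, groups)
  swapped <- setNames(ifelse(groups == "male", "female", "male"),
                      names(groups))
  sc_sw <- nb_group_score(m, swapped)
  idx <- match(sc$gene_id, sc_sw$gene_id)
  expect_equal(sc$score, sc_sw$score[idx], tolerance = 1e-9)
  expect_equal(sc$logFC, -sc_sw$logFC[idx], tolerance = 1e-9)
  expect_equal(sc$p_value, sc_sw$p_value[idx], tolerance = 1e-9)

  # permuting samples and genes leaves scores unchanged
  perm_s <- sample(colnames(m))
  perm_g <- sample(rownames(m))
  sc_p <- nb_group_score(m[perm_g, perm_s], groups[perm_s])
  expect_equal(sc_p$score[match(sc$gene_id, sc_p$gene_id)], sc$score,
               tolerance = 1e-9)
})

test_that("group sizes and labels are validated", {
  m <- random_count_matrix(20, 4, seed = 2)
  g3 <- setNames(c("a", "b", "c", "a"), colnames(m))
  expect_error(nb_group_score(m, g3), "exactly two group labels")
  g_small <- setNames(c("male", "female", "female", "female"), colnames(m))
  expect_error(nb_group_score(m, g_small), "at least 2 samples")
})

test_that("estimated log fold changes recover planted effects", {
  # planted log2 effects of 2, 4, 8; median estimate within 0.25
  for (L in c(2, 4, 8)) {
    est <- vapply(1:30, function(seed) {
      set.seed(seed * 1000 + L)
      n <- 15
      mu_f <- 50
      mu_m <- mu_f * 2^L
      males <- matrix(rnbinom(40 * n, size = 10, mu = 100), ncol = n)
      females <- matrix(rnbinom(40 * n, size = 10, mu = 100), ncol = n)
      males[1, ] <- rnbinom(n, size = 10, mu = mu_m)
      females[1, ] <- rnbinom(n, size = 10, mu = mu_f)
      rownames(males) <- rownames(females) <- paste0("g", 1:40)
      tg <- make_two_group(males, females)
      lib <- setNames(rep(1e6, 2 * n), colnames(tg$counts))
      sc <- nb_group_score(tg$counts, tg$groups, lib_size = lib)
      sc$logFC[sc$gene_id == "g1"]
    }, numeric(1))
    expect_lt(abs(median(est) - L), 0.25)
  }
})

test_that("score never decreases when male counts of a marker grow", {
  set.seed(9)
  base <- matrix(rnbinom(30 * 8, size = 10, mu = 50), nrow = 30)
  rownames(base) <- paste0("g", 1:30)
  base["g5", 5:8] <- 0
  tg <- make_two_group(base[, 1:4], base[, 5:8])
  lib <- setNames(rep(1e4, 8), colnames(tg$counts))
  scores <- vapply(c(0, 50, 200, 800), function(add) {
    m <- tg$counts
    m["g5", 1:4] <- m["g5", 1:4] + add
    sc <- nb_group_score(m, tg$groups, lib_size = lib)
    sc$score[sc$gene_id == "g5"]
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("specificity selection returns planted markers and filters leaks", {
  sim <- simulate_counts(synthetic_spec(seed = 21))
  f <- tmm_norm_factors(sim$counts)
  sc <- nb_group_score(sim$counts, sim$groups, f)
  panel <- select_sex_markers(sc, discovery_config())
  expect_setequal(panel$gene_ids, sim$truth$marker_genes)

  # a high-scoring gene expressed in one female must be excluded
  counts2 <- sim$counts
  leaky <- sim$truth$marker_genes[1]
  female_ids <- names(sim$groups)[sim$groups == "female"]
  counts2[leaky, female_ids[1]] <-
    round(50 * sim$truth$lib_sizes[female_ids[1]] / 1e6) # ~50 CPM leak
  f2 <- tmm_norm_factors(counts2)
  sc2 <- nb_group_score(counts2, sim$groups, f2)
  expect_warning(panel2 <- select_sex_markers(sc2, discovery_config()),
                 "pass the specificity")
  expect_false(leaky %in% panel2$gene_ids)
  expect_setequal(panel2$gene_ids, setdiff(sim$truth$marker_genes, leaky))
})

test_that("full discovery pipeline runs from counts + annotation", {
  sim <- simulate_counts(synthetic_spec(seed = 8))
  disc <- discover_markers(sim$counts, sim$annots, sim$groups)
  expect_setequal(disc$panel$gene_ids, sim$truth$marker_genes)
  expect_equal(exp(mean(log(disc$norm_factors))), 1, tolerance = 1e-8)

  rep_path <- withr::local_tempfile(fileext = ".tsv")
  rep_ <- discovery_report(disc$scores, disc$panel, rep_path, sim$annots)
  tab <- utils::read.table(rep_path, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), nrow(disc$scores))
  expect_true(all(diff(tab$score) <= 0))
  expect_equal(sum(tab$in_panel), length(disc$panel$gene_ids))
})

test_that("discovery report writes a header-only table for empty scores", {
  empty <- nb_group_score(random_count_matrix(5, 4, seed = 1),
                          setNames(rep(c("male", "female"), each = 2),
                                   paste0("s", 1:4)))[0, ]
  p <- withr::local_tempfile(fileext = ".tsv")
  discovery_report(empty, marker_panel("x"), p)
  lines <- readLines(p)
  expect_length(lines, 1L)
})
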