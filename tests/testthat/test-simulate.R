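test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes_per_category = c(control = 20, bi_to_mono_A2 = 20),
                    seed = 5)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
})

test_that("extending the gene list leaves earlier genes unchanged", {
  s1 <- simulate_experiment(sim_config(
    n_genes_per_category = c(control = 30), seed = 5))
  s2 <- simulate_experiment(sim_config(
    n_genes_per_category = c(control = 30, bi_to_bi_down = 10), seed = 5))
  expect_identical(s1$tables[[1]]$a1, s2$tables[[1]]$a1[1:30, ])
  expect_identical(s1$tables[[1]]$total, s2$tables[[1]]$total[1:30, ])
})

test_that("allelic counts never exceed totals", {
  sim <- small_sim()
  for (tab in sim$tables) {
    expect_true(all(tab$a1 + tab$a2 <= tab$total))
    expect_true(all(tab$a1 >= 0) && all(tab$a2 >= 0))
  }
})

test_that("control genes keep their expression across conditions", {
  sim <- simulate_experiment(sim_config(
    n_genes_per_category = c(control = 2000), seed = 9))
  tab <- sim$tables[[1]]
  wt <- tab$samples$condition == "WT"
  ratio <- mean(tab$total[, !wt]) / mean(tab$total[, wt])
  expect_gt(ratio, 0.97)
  expect_lt(ratio, 1.03)
})

test_that("planted silencing is recovered by mean-ratio estimation", {
  sim <- simulate_experiment(sim_config(
    n_genes_per_category = c(bi_to_mono_A2 = 150, bi_to_mono_A1 = 150,
                             bi_to_bi_down = 150), seed = 13))
  tab <- sim$tables[[1]]
  wt <- tab$samples$condition == "WT"
  pc <- sim$truth$genes$planted_category
  # bi_to_mono_A2 silences a1 at -3: KO/WT allele-1 ratio near 2^-3
  i <- pc == "bi_to_mono_A2"
  r <- mean(tab$a1[i, !wt]) / mean(tab$a1[i, wt])
  expect_gt(r, 0.8 * 2^-3)
  expect_lt(r, 1.2 * 2^-3)
  expect_equal(log2(r), -3, tolerance = 0.2)
  # the surviving allele is untouched
  r2 <- mean(tab$a2[i, !wt]) / mean(tab$a2[i, wt])
  expect_equal(log2(r2), 0, tolerance = 0.2)
  # bi_to_bi_down moves both alleles by down_lfc
  j <- pc == "bi_to_bi_down"
  expect_equal(log2(mean(tab$a1[j, !wt]) / mean(tab$a1[j, wt])), -0.7,
               tolerance = 0.2)
  expect_equal(log2(mean(tab$a2[j, !wt]) / mean(tab$a2[j, wt])), -0.7,
               tolerance = 0.2)
})

test_that("imprinted genes silence the maternal allele in each cross", {
  sim <- small_sim()
  truth <- sim$truth
  imp <- truth$genes$gene_id[
    truth$genes$parental_origin_mode == "imprinted_maternal"]
  eff <- truth$clone_effects
  # CaBl has a CAST mother (maternal allele a2); 9sCa a CAST father (a1)
  ca <- eff[eff$clone_id == "CaBl" & eff$gene_id %in% imp, ]
  sc <- eff[eff$clone_id == "9sCa" & eff$gene_id %in% imp, ]
  expect_true(all(ca$lost_allele == "a2"))
  expect_true(all(sc$lost_allele == "a1"))
  expect_true(all(ca$lfc_a2 == sim$config$silencing_lfc))
  expect_true(all(sc$lfc_a1 == sim$config$silencing_lfc))
})

test_that("escapee genes are X-linked with a partial Xi fraction", {
  sim <- small_sim()
  g <- sim$truth$genes
  esc <- g$planted_category %in% c("escapee", "escapee_msl2_regulated")
  expect_true(all(g$chrom[esc] == "chrX"))
  expect_true(all(g$chrom[!esc] != "chrX"))
  eff <- sim$truth$clone_effects
  e <- eff[eff$clone_id == "CaBl" & eff$gene_id %in% g$gene_id[esc], ]
  w_xi <- e$w_a2  # Xi is a2 in CaBl
  expect_true(all(w_xi > 0.15 & w_xi < 0.45))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(base_mean = 0), "base_mean")
  expect_error(sim_config(n_genes_per_category = c(nonsense = 5)),
               "unknown categories")
  expect_error(cross_info("x", "CAST", "BL6", sex = "M", xi_allele = "a1"),
               "male")
  expect_error(cross_info("x", "CAST", "CAST"), "differ")
  expect_error(sim_config(assign_rate = 0), "assign_rate")
})

test_that("methylation gain is planted on the silenced allele only", {
  sim <- small_sim()
  meth <- simulate_methylation(sim, clone_id = "CaBl", coverage = 50,
                               seed = 2)
  meth <- methylation_frequency(meth)
  g <- sim$truth$genes
  ctrl <- meth$gene_id %in% g$gene_id[g$planted_category == "control"]
  expect_equal(mean(meth$frequency[ctrl]), 0.05, tolerance = 0.05)
  # bi_to_mono_A2 silences a1: its KO a1 CpGs are hypermethylated
  bm <- meth$gene_id %in% g$gene_id[g$planted_category == "bi_to_mono_A2"]
  hi <- bm & meth$condition == "KO" & meth$allele == "a1"
  lo <- bm & !(meth$condition == "KO" & meth$allele == "a1")
  expect_equal(mean(meth$frequency[hi]), 0.6, tolerance = 0.05)
  expect_equal(mean(meth$frequency[lo]), 0.05, tolerance = 0.05)
  expect_error(simulate_methylation(sim, coverage = 0), "coverage")
})

test_that("contact simulation plants exact peak-pair enrichment", {
  m <- simulate_contacts(peaks = c(5, 12, 20), n_bins = 30, enrichment = 5)
  expect_identical(unclass(m)[5, 12], 5)
  expect_identical(unclass(m)[2, 9], 1)
  expect_equal(unclass(m), t(unclass(m)))
  flat <- simulate_contacts(peaks = c(5, 12), n_bins = 30, enrichment = 1)
  expect_true(all(unclass(flat) == 1))
  noisy <- simulate_contacts(peaks = 3, n_bins = 25, enrichment = 2,
                             noise_sd = 0.1, seed = 4)
  expect_equal(unclass(noisy), t(unclass(noisy)))
  expect_error(simulate_contacts(peaks = 40, n_bins = 30, enrichment = 2),
               "peaks outside")
  expect_error(simulate_contacts(peaks = 1, n_bins = 10, enrichment = 2),
               "n_bins")
  expect_error(simulate_contacts(peaks = 1, n_bins = 30, enrichment = 0),
               "enrichment")
})

test_that("cell simulation respects expressed alleles and the seed", {
  sim <- small_sim()
  cells <- simulate_cells(sim, n_cells = 40, detect_prob = 1,
                          clone_id = "CaBl", seed = 3)
  g <- sim$truth$genes
  ctrl <- g$gene_id[g$planted_category == "control"]
  expect_true(all(cells$a1[, ctrl] == 1L))
  expect_true(all(cells$a2[, ctrl] == 1L))
  # monoallelic-A2 genes express a2 only in WT
  mono <- g$gene_id[g$planted_category == "mono_A2_to_none"]
  expect_true(all(cells$a1[, mono] == 0L))
  expect_true(all(cells$a2[, mono] == 1L))
  c2 <- simulate_cells(sim, n_cells = 40, detect_prob = 1,
                       clone_id = "CaBl", seed = 3)
  expect_identical(cells, c2)
  expect_error(simulate_cells(sim, n_cells = 0, detect_prob = 0.5), "n_cells")
  expect_error(simulate_cells(sim, n_cells = 5, detect_prob = 0), "detect_prob")
})
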