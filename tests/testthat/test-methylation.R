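test_that("methylation frequency is M over coverage with undefined zeros", {
  tab <- data.frame(chrom = "chr1", pos = 1:3, allele = "a1",
                    count_M = c(8L, 0L, 50L), count_U = c(2L, 0L, 0L))
  f <- methylation_frequency(tab)
  expect_equal(f$frequency, c(0.8, NA, 1.0))
  expect_equal(f$undefined, c(FALSE, TRUE, FALSE))
  tab$count_M[1] <- -1L
  expect_error(methylation_frequency(tab), "non-negative")
})

make_cpg <- function(pos, M, U, chrom = "chr1", allele = "a1") {
  data.frame(chrom = chrom, pos = pos, allele = allele,
             count_M = M, count_U = U)
}

test_that("DML p-values match the exact hypergeometric computation", {
  wt <- make_cpg(100L, 50L, 0L)
  ko <- make_cpg(100L, 0L, 50L)
  res <- call_dml(wt, ko)
  expect_equal(res$p, 2 / choose(100, 50), tolerance = 1e-9)
  expect_true(res$is_dml)
  expect_equal(res$delta_f, -1)
})

test_that("identical methylation yields p = 1 and no call", {
  wt <- make_cpg(c(10L, 20L), c(25L, 5L), c(25L, 45L))
  res <- call_dml(wt, wt)
  expect_equal(res$p, c(1, 1))
  expect_false(any(res$is_dml))
  expect_equal(res$delta_f, c(0, 0))
})

test_that("low-coverage CpGs are excluded and replicates pooled", {
  wt <- rbind(make_cpg(10L, 3L, 2L), make_cpg(10L, 2L, 3L),  # pooled 5/5
              make_cpg(20L, 2L, 3L))                          # coverage 5
  ko <- rbind(make_cpg(10L, 9L, 1L), make_cpg(20L, 4L, 1L))
  res <- call_dml(wt, ko)
  expect_true(res$tested[res$pos == 10])
  expect_false(res$tested[res$pos == 20])
  expect_true(is.na(res$p[res$pos == 20]))
  expect_equal(res$coverage_wt[res$pos == 10], 10)
  expect_error(call_dml(make_cpg(1L, 5L, 5L),
                        make_cpg(2L, 5L, 5L)), "no overlapping CpGs")
})

test_that("DML p equals exhaustive enumeration for small tables", {
  set.seed(19)
  for (rep in 1:60) {
    mw <- sample(0:15, 1); uw <- sample(0:15, 1)
    mk <- sample(0:15, 1); uk <- sample(0:15, 1)
    if (mw + uw == 0 || mk + uk == 0) next
    res <- call_dml(make_cpg(5L, mw, uw), make_cpg(5L, mk, uk),
                    min_coverage = 0L)
    expect_equal(res$p, fisher_p_enum(mw, uw, mk, uk), tolerance = 1e-9)
  }
})

test_that("region classification applies bands, size and TSS filters", {
  tss <- data.frame(chrom = "chr1", tss = 1200L)
  cpg <- function(pos, f) {
    data.frame(chrom = "chr1", pos = pos, frequency = f, coverage = 50L)
  }
  # 10 CpGs at 0.97 spanning ~500 bp around the TSS: one fully region
  freqs <- cpg(seq(1000L, 1500L, length.out = 10L), 0.97)
  regions <- classify_methylation_regions(freqs, tss)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$class, "fully")
  expect_equal(regions$n_cpg, 10)
  # same CpGs spread over 5000 bp: each pair is > merge_gap apart
  wide <- cpg(seq(1000L, 6000L, length.out = 10L), 0.97)
  expect_equal(nrow(classify_methylation_regions(wide, tss)), 0)
  # no TSS overlap
  far_tss <- data.frame(chrom = "chr1", tss = 99000L)
  expect_equal(nrow(classify_methylation_regions(freqs, far_tss)), 0)
  # low and unmethylated bands are kept apart
  mix <- rbind(cpg(seq(1000L, 1400L, by = 100L), 0.3),
               cpg(seq(1450L, 1850L, by = 100L), 0.05))
  two_tss <- rbind(tss, data.frame(chrom = "chr1", tss = 1650L))
  r <- classify_methylation_regions(mix, two_tss)
  expect_equal(sort(r$class), c("low", "un"))
  # low-coverage CpGs are dropped entirely
  weak <- cpg(seq(1000L, 1500L, length.out = 10L), 0.97)
  weak$coverage <- 5L
  expect_equal(nrow(classify_methylation_regions(weak, tss)), 0)
  expect_equal(nrow(classify_methylation_regions(freqs[0, ], tss)), 0)
})

test_that("TF-binding/methylation anticorrelation applies both filters", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(100L, 500L, 900L),
                      end = c(300L, 700L, 1100L),
                      lfc = c(1.5, 0.5, -2))
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(150L, 600L, 950L, 1000L),
                     delta_f = c(-0.4, -0.6, 0.3, 0.1))
  res <- tf_meth_anticorrelation(peaks, cpgs)
  # peak 2 fails |lfc| > 1; CpG 4 fails |delta_f| > 0.25
  expect_equal(nrow(res$pairs), 2)
  expect_true(all(res$pairs$concordant))
  expect_equal(res$fraction_concordant, 1)
  # a concordant-signed pair is not anticorrelated
  cpgs2 <- data.frame(chrom = "chr1", pos = 150L, delta_f = 0.4)
  res2 <- tf_meth_anticorrelation(peaks, cpgs2)
  expect_false(res2$pairs$concordant)
  # empty selections give an NA summary
  res3 <- tf_meth_anticorrelation(peaks[peaks$lfc > 10, ], cpgs)
  expect_true(is.na(res3$fraction_concordant))
})

test_that("planted methylation gain is called as DML with high specificity", {
  sim <- small_sim()
  meth <- simulate_methylation(sim, clone_id = "CaBl", seed = 8)
  dml <- call_dml(meth[meth$condition == "WT", ],
                  meth[meth$condition == "KO", ])
  truth <- clone_truth(sim, "CaBl")
  silenced <- truth[!is.na(truth$lost_allele) & truth$lfc_a1 < 0 |
                      !is.na(truth$lost_allele) & truth$lfc_a2 < 0, ]
  key <- paste(meth$chrom, meth$pos, meth$allele)
  planted_keys <- unique(key[meth$gene_id %in% silenced$gene_id &
                               meth$allele == silenced$lost_allele[
                                 match(meth$gene_id, silenced$gene_id)]])
  res_key <- paste(dml$chrom, dml$pos, dml$allele)
  planted <- res_key %in% planted_keys
  # the BH step-up over the mixed CpG set tightens the effective per-CpG
  # threshold below the nominal FDR, so power sits a little under the
  # raw-p binomial power (~0.97 at this coverage and effect)
  expect_gte(mean(dml$is_dml[planted]), 0.90)
  expect_lte(mean(dml$is_dml[!planted]), 0.001)
})
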