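test_that("k-means recovers planted separable clusters", {
  set.seed(2)
  a <- cbind(rnorm(40, -3, 0.1), rnorm(40, 0, 0.1))
  b <- cbind(rnorm(40, 0, 0.1), rnorm(40, -3, 0.1))
  labels <- cluster_allelic_fc(rbind(a, b), k = 2, seed = 6)
  expect_length(unique(labels[1:40]), 1)
  expect_length(unique(labels[41:80]), 1)
  expect_false(labels[1] == labels[41])
})

test_that("k-means is seeded and validates k", {
  set.seed(3)
  m <- matrix(rnorm(60), ncol = 2)
  expect_identical(as.integer(cluster_allelic_fc(m, k = 3, seed = 9)),
                   as.integer(cluster_allelic_fc(m, k = 3, seed = 9)))
  expect_true(all(cluster_allelic_fc(m, k = 1, seed = 1) == 1))
  expect_error(cluster_allelic_fc(m, k = 31), "exceeds")
  m[1, 1] <- NA
  expect_message(cluster_allelic_fc(m, k = 2, seed = 1), "imputing")
})

cabl_f <- cross_info("CaBl_f", "CAST", "BL6", sex = "F", xi_allele = "a2")
blca_f <- cross_info("BlCa_f", "BL6", "CAST", sex = "F", xi_allele = "a1")
cabl_m <- cross_info("CaBl_m", "CAST", "BL6", sex = "M")

calls_of <- function(gene_id, category) {
  data.frame(gene_id = gene_id, category = category)
}

test_that("reciprocal maternal loss is imprinting-like reversed allele", {
  # CaBl (CAST mother) loses a2 = maternal; BlCa (CAST father) loses a1
  ca <- calls_of("g1", "bi_to_mono_A1")  # surviving a1, lost a2
  bl <- calls_of("g1", "bi_to_mono_A2")  # lost a1
  cons <- classify_cross_clone_consistency(ca, bl, cabl_f, blca_f)
  expect_equal(cons$mode, "reversed_allele")
  expect_equal(cons$origin_a, "maternal")
  expect_equal(cons$origin_b, "maternal")
  expect_true(cons$origin_consistent)
  expect_equal(cons$label, "imprinting_like")
})

test_that("shared strain-allele loss is same_allele", {
  ca <- calls_of("g1", "bi_to_mono_A2")  # lost a1 in both
  bl <- calls_of("g1", "bi_to_mono_A2")
  cons <- classify_cross_clone_consistency(ca, bl, cabl_f, blca_f)
  expect_equal(cons$mode, "same_allele")
  expect_false(cons$origin_consistent)  # a1 is paternal in CaBl, maternal in BlCa
})

test_that("same-cross clones with opposite losses are random-monoallelic-like", {
  m <- calls_of("g1", "bi_to_mono_A1")
  f <- calls_of("g1", "bi_to_mono_A2")
  cons <- classify_cross_clone_consistency(m, f, cabl_m, cabl_f)
  expect_equal(cons$mode, "reversed_allele")
  expect_equal(cons$label, "random_monoallelic_like")
})

test_that("swapping the clone arguments leaves the mode unchanged", {
  ca <- calls_of(c("g1", "g2"), c("bi_to_mono_A1", "bi_to_mono_A2"))
  bl <- calls_of(c("g1", "g2"), c("bi_to_mono_A2", "bi_to_mono_A2"))
  c1 <- classify_cross_clone_consistency(ca, bl, cabl_f, blca_f)
  c2 <- classify_cross_clone_consistency(bl, ca, blca_f, cabl_f)
  expect_equal(c1$mode, c2$mode)
  expect_equal(c1$origin_consistent, c2$origin_consistent)
})

test_that("only genes bi-to-mono in both clones are classified", {
  ca <- calls_of(c("g1", "g2"), c("bi_to_mono_A1", "bi_to_bi_down"))
  bl <- calls_of(c("g1", "g2"), c("bi_to_mono_A1", "bi_to_mono_A2"))
  cons <- classify_cross_clone_consistency(ca, bl, cabl_f, blca_f)
  expect_equal(cons$gene_id, "g1")
})

test_that("planted imprinted genes classify as reversed maternal loss", {
  sim <- small_sim()
  calls <- small_calls()
  crosses <- sim$config$crosses
  cons <- classify_cross_clone_consistency(calls$CaBl, calls$`9sCa`,
                                           crosses[[1]], crosses[[2]])
  imp <- sim$truth$genes$gene_id[
    sim$truth$genes$parental_origin_mode == "imprinted_maternal"]
  hit <- cons[cons$gene_id %in% imp, ]
  expect_gte(nrow(hit) / length(imp), 0.9)
  expect_gte(mean(hit$mode == "reversed_allele" &
                    hit$origin_a == "maternal" &
                    hit$origin_b == "maternal"), 0.9)
  # strain-consistent genes stay same_allele
  fixed <- sim$truth$genes$gene_id[
    sim$truth$genes$planted_category %in% c("bi_to_mono_A1", "bi_to_mono_A2")]
  hf <- cons[cons$gene_id %in% fixed, ]
  expect_gte(mean(hf$mode == "same_allele"), 0.95)
})

test_that("the k-means consistency variant agrees with the rule when separable", {
  set.seed(12)
  n <- 30
  # same-allele genes: a1 lost in both clones; reversed: a1 in A, a2 in B
  same <- cbind(rnorm(n, -3, 0.1), rnorm(n, 0, 0.1),
                rnorm(n, -3, 0.1), rnorm(n, 0, 0.1))
  rev_ <- cbind(rnorm(n, -3, 0.1), rnorm(n, 0, 0.1),
                rnorm(n, 0, 0.1), rnorm(n, -3, 0.1))
  x <- rbind(same, rev_)
  lab <- consistency_kmeans(x[, 1:2], x[, 3:4], seed = 7)
  expect_true(all(lab[1:n] == "same_allele"))
  expect_true(all(lab[(n + 1):(2 * n)] == "reversed_allele"))
})

test_that("Fisher enrichment matches symmetry and hand-enumerated cases", {
  u <- sprintf("g%03d", 1:20)
  res <- fisher_enrichment(u[1:10], c(u[1:5], u[11:15]), u)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  # disjoint perfect association: p = 2 / choose(20, 10)
  res2 <- fisher_enrichment(u[1:10], u[1:10], u)
  expect_equal(res2$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(res2$haldane)
  expect_error(fisher_enrichment("x", "x", character()), "empty universe")
  expect_error(fisher_enrichment("zz", u[1], u), "not contained")
})

test_that("Fisher p equals exhaustive enumeration for small tables", {
  set.seed(15)
  for (rep in 1:80) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    cc <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b + cc + d == 0) next
    u <- sprintf("u%03d", seq_len(a + b + cc + d))
    q <- u[seq_len(a + b)]
    ann <- c(u[seq_len(a)], u[a + b + seq_len(cc)])
    res <- fisher_enrichment(q, ann, u)
    expect_equal(res$p, fisher_p_enum(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("haploinsufficiency summary matches hand counts on a toy set", {
  u <- sprintf("g%03d", 1:200)
  hi <- data.frame(gene_id = u[1:100],
                   hi_score = rep(c(0.9, 0.2), 50),
                   triplosensitive = rep(c(1, 0), 50))
  calls <- data.frame(gene_id = u[c(1:20, 101:110)],
                      category = rep(c("bi_to_mono_A1", "control"),
                                     c(20, 10)))
  s <- haploinsufficiency_summary(calls, hi, u)
  bm <- s[s$category == "bi_to_mono_A1", ]
  expect_equal(bm$n, 20)
  expect_equal(bm$n_hi, 20)
  expect_equal(bm$frac_hi, 1)
  expect_gt(bm$odds_ratio, 1)
  ctrl <- s[s$category == "control", ]
  expect_equal(ctrl$n_hi, 0)
  expect_equal(ctrl$frac_hi, 0)
  expect_error(haploinsufficiency_summary(
    calls, rbind(hi, hi[1, ]), u), "duplicated")
  empty <- haploinsufficiency_summary(calls, hi[0, ], u)
  expect_true(all(empty$frac_hi == 0))
  expect_true(all(empty$p == 1))
})
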