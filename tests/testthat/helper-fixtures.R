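# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Moderate two-clone simulation exercising every planted category.
small_sim <- function() memo("small_sim", {
  simulate_experiment(sim_config(
    n_genes_per_category = c(control = 150, bi_to_bi_down = 60,
                             bi_to_mono_A1 = 60, bi_to_mono_A2 = 60,
                             mono_A1_to_none = 60, mono_A2_to_none = 60,
                             bi_to_mono_imprinted_maternal = 30,
                             bi_to_mono_imprinted_paternal = 30,
                             bi_to_mono_random = 30,
                             escapee = 30, escapee_msl2_regulated = 30),
    seed = 42))
})

small_suites <- function() memo("small_suites", {
  lapply(small_sim()$tables, run_de_suite)
})

small_calls <- function() memo("small_calls", {
  sim <- small_sim()
  suites <- small_suites()
  lapply(names(suites), function(cl) {
    wt <- compute_wt_allele_stats(sim$tables[[cl]],
                                  suites[[cl]]$size_factors$allelic)
    assign_categories(suites[[cl]], wt)
  }) |> stats::setNames(names(suites))
})

# Expected per-clone truth aligned to a table's gene order.
clone_truth <- function(sim, clone_id) {
  e <- sim$truth$clone_effects
  e <- e[e$clone_id == clone_id, ]
  e[match(sim$tables[[clone_id]]$gene_id, e$gene_id), ]
}

# Hand-built DESuiteResult-shaped object for decision-tree tests.
fake_suite <- function(gene_id, std_q = 1, std_lfc = 0,
                       a1_p = 1, a1_lfc = 0, a2_p = 1, a2_lfc = 0,
                       as_p = 1, as_lfc = 0, n_allelic_cols = 4L) {
  n <- length(gene_id)
  mk <- function(lfc, p, q = adjust_bh(p)) {
    data.frame(gene_id = gene_id, base_mean = 100, log2FC = lfc, SE = 0.1,
               stat = lfc / 0.1, p = p, q = q, tested = TRUE)
  }
  structure(list(standard = mk(std_lfc, std_q, std_q),
                 allele1 = mk(a1_lfc, a1_p),
                 allele2 = mk(a2_lfc, a2_p),
                 allele_specific = mk(as_lfc, as_p),
                 size_factors = list(total = NULL,
                                     allelic = rep(1, n_allelic_cols))),
            class = "DESuiteResult")
}

# Exact two-sided Fisher p by exhaustive hypergeometric enumeration.
fisher_p_enum <- function(a, b, c, d) {
  R1 <- a + b; C1 <- a + c; N <- a + b + c + d
  k <- max(0L, R1 + C1 - N):min(R1, C1)
  pr <- stats::dhyper(k, C1, N - C1, R1)
  obs <- stats::dhyper(a, C1, N - C1, R1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Independent step-up BH reference.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Full-size default experiment used by the acceptance checks.
default_run <- function() memo("default_run", {
  sim <- simulate_experiment(sim_config(seed = 20240101))
  suites <- lapply(sim$tables, run_de_suite)
  calls <- lapply(names(suites), function(cl) {
    wt <- compute_wt_allele_stats(sim$tables[[cl]],
                                  suites[[cl]]$size_factors$allelic)
    assign_categories(suites[[cl]], wt)
  })
  names(calls) <- names(suites)
  list(sim = sim, suites = suites, calls = calls)
})

# Handcrafted X-chromosome table: Xi = a2, constant WT counts so the
# normalized WT means are exact under unit size factors.
make_x_fixture <- function() {
  genes <- sprintf("xg%02d", 1:10)
  samples <- data.frame(sample_id = c("w1", "w2", "k1", "k2"),
                        clone_id = "femX", condition = c("WT", "WT", "KO", "KO"),
                        replicate = c(1, 2, 1, 2))
  #           xi(a2) active(a1)  expectation
  wt_a2 <- c(15,  8, 15, 15, 95, 12, 10, 90, 11,  50)
  wt_a1 <- c(50, 20, 50, 50,  5, 150, 40, 10, 11, 50)
  xi_lfc <- c(-1, -3, -2.5, -1.5, -3, -3, -3, -3, -2.1, 0)
  a1 <- cbind(wt_a1, wt_a1, wt_a1, wt_a1)
  a2 <- cbind(wt_a2, wt_a2, wt_a2, wt_a2)
  tab <- allele_count_table(genes, samples, a1, a2, a1 + a2 + 20L)
  suite <- fake_suite(genes, a2_p = 1e-4, a2_lfc = xi_lfc,
                      n_allelic_cols = 8L)
  ann <- data.frame(gene_id = genes,
                    chrom = c(rep("chrX", 9), "chr7"))
  cross <- cross_info("femX", "CAST", "BL6", sex = "F", xi_allele = "a2")
  list(tab = tab, suite = suite, ann = ann, cross = cross)
}
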