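#' Simulate an allele-resolved hybrid knockout experiment
#'
#' Generates one \code{AlleleCountTable} per clone plus a ground-truth record
#' of every planted effect. Counts are drawn at the allele level from
#' negative binomials (variance = mu + alpha mu^2, alpha shared across the
#' alleles of a gene), then an unassigned-read component is added so totals
#' exceed allelic sums, emulating SNP-assignment loss. Each gene draws from
#' its own seeded substream, so extending the gene list leaves earlier genes
#' byte-identical.
#'
#' The planted wild-type allelic weights and knockout log2 fold changes per
#' clone are recorded in \code{truth$clone_effects} together with the lost
#' allele and the category a perfect classifier should recover in that clone
#' (which differs from the global planted category for imprinted-like and
#' random-monoallelic genes, whose lost strain allele depends on the cross).
#'
#' @param config A \code{\link{sim_config}}.
#' @return list of class \code{ase_simulation} with elements \code{tables}
#'   (named list of \code{AlleleCountTable}, one per clone), \code{truth}
#'   (list with \code{genes} and \code{clone_effects} data.frames) and
#'   \code{config}.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- .build_truth(config)
  genes <- truth$genes
  eff <- truth$clone_effects
  n_rep <- config$n_replicates
  n_samp <- 2L * n_rep
  sf <- config$library_size_factors
  if (is.null(sf)) sf <- rep(1, n_samp)
  sf <- rep_len(sf, n_samp)
  is_ko <- rep(c(0, 1), each = n_rep)
  alpha <- config$dispersion

  draw <- function(mu) {
    if (alpha > 1e-12) stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
    else stats::rpois(length(mu), mu)
  }

  tables <- list()
  for (cr in config$crosses) {
    cid <- cr$clone_id
    samples <- data.frame(
      sample_id = paste(cid, rep(c("WT", "KO"), each = n_rep),
                        rep(seq_len(n_rep), 2L), sep = "_"),
      clone_id = cid,
      condition = rep(c("WT", "KO"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2L))
    e <- eff[eff$clone_id == cid, ]
    e <- e[match(genes$gene_id, e$gene_id), ]
    ng <- nrow(genes)
    a1 <- a2 <- tot <- matrix(0L, ng, n_samp)
    for (g in seq_len(ng)) {
      set.seed(.gene_seed(config$seed, g, which = 2L))
      fc1 <- 2^(e$lfc_a1[g] * is_ko)
      fc2 <- 2^(e$lfc_a2[g] * is_ko)
      mu1 <- sf * config$base_mean * config$assign_rate * e$w_a1[g] * fc1
      mu2 <- sf * config$base_mean * config$assign_rate * e$w_a2[g] * fc2
      muu <- sf * config$base_mean * (1 - config$assign_rate) *
        (e$w_a1[g] * fc1 + e$w_a2[g] * fc2)
      k1 <- draw(mu1); k2 <- draw(mu2); ku <- draw(muu)
      a1[g, ] <- k1; a2[g, ] <- k2; tot[g, ] <- k1 + k2 + ku
    }
    tables[[cid]] <- allele_count_table(genes$gene_id, samples, a1, a2, tot)
  }
  structure(list(tables = tables, truth = truth, config = config),
            class = "ase_simulation")
}

# Deterministic per-gene substream seed; `which` separates the draw phases
# (truth randomization vs counts) so they cannot alias.
.gene_seed <- function(seed, gene_index, which = 1L) {
  (as.double(seed) + 1000003 * gene_index + 7919 * which) %% 2147483647
}

.build_truth <- function(config) {
  n_cat <- config$n_genes_per_category
  cats <- rep(names(n_cat), n_cat)
  ng <- length(cats)
  if (ng == 0L) stop("no genes requested")
  gene_id <- sprintf("gene_%05d", seq_len(ng))
  origin <- rep("none", ng)
  origin[cats == "bi_to_mono_imprinted_maternal"] <- "imprinted_maternal"
  origin[cats == "bi_to_mono_imprinted_paternal"] <- "imprinted_paternal"
  origin[cats == "bi_to_mono_random"] <- "random_per_clone"
  is_x <- cats %in% c("escapee", "escapee_msl2_regulated")
  chrom <- ifelse(is_x, "chrX", paste0("chr", 1L + (seq_len(ng) - 1L) %% 19L))
  tss <- integer(ng)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    tss[idx] <- 100000L + 50000L * (seq_along(idx) - 1L)
  }
  strand <- rep(c("+", "-"), length.out = ng)
  genes <- data.frame(gene_id = gene_id, planted_category = cats,
                      parental_origin_mode = origin, chrom = chrom,
                      tss = tss, strand = strand)

  eff <- list()
  for (cr in config$crosses) {
    w1 <- rep(0.5, ng); w2 <- rep(0.5, ng)
    l1 <- numeric(ng); l2 <- numeric(ng)
    lost <- rep(NA_character_, ng)
    mat_al <- maternal_allele(cr)
    for (g in seq_len(ng)) {
      set.seed(.gene_seed(config$seed, g, which = 1L))
      u_xi <- stats::runif(1, 0.15, 0.45)   # escapee Xi expressed fraction
      rand_lost <- sample(c("a1", "a2"), length(config$crosses), replace = TRUE)
      ci <- match(cr$clone_id, vapply(config$crosses, `[[`, "", "clone_id"))
      cat_g <- cats[g]
      if (cat_g == "bi_to_bi_down") {
        l1[g] <- l2[g] <- config$down_lfc
      } else if (cat_g == "bi_to_mono_A2") {
        lost[g] <- "a1"
      } else if (cat_g == "bi_to_mono_A1") {
        lost[g] <- "a2"
      } else if (cat_g == "mono_A1_to_none") {
        w1[g] <- 1 - config$mono_minor_frac; w2[g] <- config$mono_minor_frac
        lost[g] <- "a1"
      } else if (cat_g == "mono_A2_to_none") {
        w1[g] <- config$mono_minor_frac; w2[g] <- 1 - config$mono_minor_frac
        lost[g] <- "a2"
      } else if (cat_g == "bi_to_mono_imprinted_maternal") {
        lost[g] <- mat_al
      } else if (cat_g == "bi_to_mono_imprinted_paternal") {
        lost[g] <- setdiff(c("a1", "a2"), mat_al)
      } else if (cat_g == "bi_to_mono_random") {
        lost[g] <- rand_lost[ci]
      } else if (cat_g %in% c("escapee", "escapee_msl2_regulated")) {
        if (cr$xi_allele == "none") {
          # male clone: single X, expressed from the maternal allele only
          if (mat_al == "a1") { w1[g] <- 1; w2[g] <- 0 }
          else { w1[g] <- 0; w2[g] <- 1 }
        } else {
          if (cr$xi_allele == "a1") { w1[g] <- u_xi; w2[g] <- 1 - u_xi }
          else { w1[g] <- 1 - u_xi; w2[g] <- u_xi }
          if (cat_g == "escapee_msl2_regulated") lost[g] <- cr$xi_allele
        }
      }
      if (!is.na(lost[g])) {
        if (lost[g] == "a1") l1[g] <- config$silencing_lfc
        else l2[g] <- config$silencing_lfc
      }
    }
    expected <- cats
    flip <- origin != "none"
    expected[flip] <- ifelse(lost[flip] == "a1", "bi_to_mono_A2", "bi_to_mono_A1")
    eff[[cr$clone_id]] <- data.frame(
      gene_id = gene_id, clone_id = cr$clone_id,
      w_a1 = w1, w_a2 = w2, lfc_a1 = l1, lfc_a2 = l2,
      lost_allele = lost, expected_category = expected)
  }
  list(genes = genes, clone_effects = do.call(rbind, eff))
}

#' Simulate per-CpG allelic methylation around gene promoters
#'
#' Places CpGs inside TSS windows and draws methylated counts binomially.
#' Active alleles (and both alleles of unaffected genes, in both conditions)
#' methylate at a low background frequency; the silenced allele of genes
#' undergoing a bi-to-mono transition gains methylation in the knockout,
#' emulating promoter methylation appearing on the allele that loses
#' transcription-factor binding.
#'
#' @param sim An \code{ase_simulation} (or its \code{truth} element).
#' @param clone_id Clone to simulate; default the first clone.
#' @param n_cpg_per_gene CpGs per promoter (default 10).
#' @param coverage Reads per CpG per allele per condition (default 50).
#' @param f_low,f_high Background and gained methylation frequencies
#'   (defaults 0.05 and 0.6).
#' @param tss_window Half-width of the promoter window in bp (default 100).
#' @param seed Integer seed.
#' @return data.frame (CpG methylation table) with columns \code{chrom},
#'   \code{pos}, \code{allele}, \code{condition}, \code{gene_id},
#'   \code{count_M}, \code{count_U}.
#' @export
simulate_methylation <- function(sim, clone_id = NULL, n_cpg_per_gene = 10L,
                                 coverage = 50L, f_low = 0.05, f_high = 0.6,
                                 tss_window = 100L, seed = 1L) {
  truth <- if (inherits(sim, "ase_simulation")) sim$truth else sim
  if (coverage < 1L) stop("coverage must be >= 1")
  stopifnot(f_low >= 0, f_low <= 1, f_high >= 0, f_high <= 1,
            n_cpg_per_gene >= 1L)
  genes <- truth$genes
  eff <- truth$clone_effects
  if (is.null(clone_id)) clone_id <- eff$clone_id[1L]
  e <- eff[eff$clone_id == clone_id, ]
  if (!nrow(e)) stop("unknown clone_id: ", clone_id)
  e <- e[match(genes$gene_id, e$gene_id), ]
  set.seed(seed)
  out <- vector("list", nrow(genes))
  offs <- round(seq(-tss_window, tss_window, length.out = n_cpg_per_gene))
  for (g in seq_len(nrow(genes))) {
    pos <- genes$tss[g] + offs
    rec <- expand.grid(pos = pos, allele = c("a1", "a2"),
                       condition = c("WT", "KO"), stringsAsFactors = FALSE)
    silenced <- e$lost_allele[g]
    f <- ifelse(rec$condition == "KO" & !is.na(silenced) &
                  rec$allele == silenced & abs(
                    ifelse(silenced == "a1", e$lfc_a1[g], e$lfc_a2[g])) > 0,
                f_high, f_low)
    m <- stats::rbinom(nrow(rec), coverage, f)
    out[[g]] <- data.frame(chrom = genes$chrom[g], pos = rec$pos,
                           allele = rec$allele, condition = rec$condition,
                           gene_id = genes$gene_id[g],
                           count_M = m, count_U = coverage - m)
  }
  do.call(rbind, out)
}

#' Simulate a binned contact matrix with planted peak-pair enrichment
#'
#' Builds a symmetric matrix with a constant baseline; every pair of bins
#' that both contain at least one peak is raised by the enrichment factor.
#' Optional Gaussian noise is added symmetrically and clamped at zero.
#'
#' @param peaks Integer vector of 1-based bin indices containing a peak.
#' @param n_bins Number of bins (>= 20).
#' @param enrichment Multiplier on peak-pair entries (> 0).
#' @param baseline Baseline contact value (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0, none).
#' @param bin_size Bin width in bp, recorded as an attribute (default 1e4).
#' @param seed Integer seed (used only when noise_sd > 0).
#' @return Symmetric numeric matrix with attribute \code{bin_size}.
#' @export
simulate_contacts <- function(peaks, n_bins, enrichment, baseline = 1,
                              noise_sd = 0, bin_size = 1e4, seed = 1L) {
  if (n_bins < 20L) stop("n_bins must be >= 20")
  if (enrichment <= 0) stop("enrichment must be positive")
  peaks <- as.integer(peaks)
  if (length(peaks) && (min(peaks) < 1L || max(peaks) > n_bins)) {
    stop("peaks outside [1, n_bins]")
  }
  m <- matrix(baseline, n_bins, n_bins)
  if (length(peaks)) m[peaks, peaks] <- baseline * enrichment
  if (noise_sd > 0) {
    set.seed(seed)
    eps <- matrix(stats::rnorm(n_bins^2, 0, noise_sd), n_bins, n_bins)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    m <- pmax(m + eps, 0)
  }
  attr(m, "bin_size") <- bin_size
  m
}

#' Simulate per-cell allelic detection
#'
#' For each cell and gene, each expressed allele is detected with probability
#' \code{detect_prob}; silenced alleles are never detected. Expression status
#' comes from the simulation truth for the chosen clone and condition: an
#' allele is expressed when its wild-type weight is at least 0.1 and, in the
#' knockout, its planted log2FC is above -1.
#'
#' @param sim An \code{ase_simulation} (or its \code{truth}).
#' @param n_cells Number of cells (> 0).
#' @param detect_prob Detection probability in (0, 1].
#' @param clone_id Clone; default the first.
#' @param condition "WT" (default) or "KO".
#' @param seed Integer seed.
#' @return list of class \code{CellAlleleExpression} with binary matrices
#'   \code{a1}, \code{a2} (cells x genes) and \code{gene_id}.
#' @export
simulate_cells <- function(sim, n_cells, detect_prob, clone_id = NULL,
                           condition = "WT", seed = 1L) {
  truth <- if (inherits(sim, "ase_simulation")) sim$truth else sim
  if (n_cells <= 0L) stop("n_cells must be positive")
  if (detect_prob <= 0 || detect_prob > 1) stop("detect_prob must be in (0, 1]")
  eff <- truth$clone_effects
  if (is.null(clone_id)) clone_id <- eff$clone_id[1L]
  e <- eff[eff$clone_id == clone_id, ]
  if (!nrow(e)) stop("unknown clone_id: ", clone_id)
  ko <- condition == "KO"
  expr1 <- e$w_a1 >= 0.1 & (!ko | e$lfc_a1 > -1)
  expr2 <- e$w_a2 >= 0.1 & (!ko | e$lfc_a2 > -1)
  set.seed(seed)
  ng <- nrow(e)
  d1 <- matrix(stats::rbinom(n_cells * ng, 1L, detect_prob), n_cells, ng)
  d2 <- matrix(stats::rbinom(n_cells * ng, 1L, detect_prob), n_cells, ng)
  d1[, !expr1] <- 0L
  d2[, !expr2] <- 0L
  colnames(d1) <- colnames(d2) <- e$gene_id
  structure(list(a1 = d1, a2 = d2, gene_id = e$gene_id,
                 clone_id = clone_id, condition = condition),
            class = "CellAlleleExpression")
}
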