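#' Thresholds for the allelic category decision tree
#'
#' Bundles every cut-off used by \code{\link{assign_categories}} and the
#' escapee/consistency rules: the standard q-value and per-allele p-value
#' cut-offs, the allele-specific candidate gate (p and absolute log2FC), the
#' strict complete-silencing log2FC, the wild-type allele-2/allele-1 log2
#' ratio bound separating monoallelic from biallelic baselines, the minimum
#' wild-type minor-allele fraction, the control-set size and the pseudocount
#' used inside the wild-type log ratio.
#'
#' @param standard_q Standard-mode q cut-off (default 0.01).
#' @param allelic_p Per-allele p cut-off (default 0.01).
#' @param as_p Allele-specific p cut-off (default 0.05).
#' @param as_abs_lfc Allele-specific absolute log2FC cut-off (default 0.5).
#' @param strict_lfc Complete-silencing log2FC (default -2).
#' @param wt_ratio_bound WT log2(a2/a1) bound (default 1; the mono gates use
#'   +/- this value).
#' @param wt_frac_min Minimum WT minor-allele fraction for a biallelic
#'   baseline (default 0.1).
#' @param n_controls Control-set size (default 300).
#' @param pseudocount Pseudocount inside the WT log ratio (default 1).
#' @return list of class \code{ase_thresholds}.
#' @export
ase_thresholds <- function(standard_q = 0.01, allelic_p = 0.01, as_p = 0.05,
                           as_abs_lfc = 0.5, strict_lfc = -2,
                           wt_ratio_bound = 1, wt_frac_min = 0.1,
                           n_controls = 300L, pseudocount = 1) {
  stopifnot(standard_q > 0, standard_q < 1, allelic_p > 0, allelic_p < 1,
            as_p > 0, as_p < 1, wt_frac_min > 0, wt_frac_min < 0.5,
            as_abs_lfc >= 0, strict_lfc < 0, wt_ratio_bound > 0,
            n_controls >= 1L, pseudocount >= 0)
  structure(list(standard_q = standard_q, allelic_p = allelic_p, as_p = as_p,
                 as_abs_lfc = as_abs_lfc, strict_lfc = strict_lfc,
                 wt_ratio_bound = wt_ratio_bound, wt_frac_min = wt_frac_min,
                 n_controls = as.integer(n_controls),
                 pseudocount = pseudocount),
            class = "ase_thresholds")
}

#' Wild-type allelic baseline statistics
#'
#' Computes, per gene, the mean wild-type normalized count on each allele,
#' the log2 allele-2/allele-1 ratio (pseudocount applied inside the log
#' only), and the allelic fractions (raw means, no pseudocount). Genes with
#' zero on both alleles get NaN statistics and are unclassifiable.
#'
#' @param table An \code{AlleleCountTable}.
#' @param size_factors Size factors for the sample-by-allele layout (a1
#'   columns then a2 columns); default estimated from the layout.
#' @param pseudocount Pseudocount for the log ratio (default 1).
#' @return data.frame: gene_id, wt_mean_a1, wt_mean_a2, wt_log2_ratio,
#'   wt_frac_a1, wt_frac_a2.
#' @export
compute_wt_allele_stats <- function(table, size_factors = NULL,
                                    pseudocount = 1) {
  stopifnot(inherits(table, "AlleleCountTable"))
  wt <- table$samples$condition == "WT"
  if (!any(wt)) stop("no WT samples")
  lay <- allele_layout(table)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(lay$counts)
  stopifnot(length(size_factors) == ncol(lay$counts))
  norm <- sweep(lay$counts, 2L, size_factors, "/")
  wt_cols <- lay$columns$condition == "WT"
  m1 <- rowMeans(norm[, wt_cols & lay$columns$allele == "a1", drop = FALSE])
  m2 <- rowMeans(norm[, wt_cols & lay$columns$allele == "a2", drop = FALSE])
  tot <- m1 + m2
  frac1 <- ifelse(tot > 0, m1 / tot, NaN)
  data.frame(gene_id = table$gene_id, wt_mean_a1 = m1, wt_mean_a2 = m2,
             wt_log2_ratio = ifelse(tot > 0,
                                    log2((m2 + pseudocount) / (m1 + pseudocount)),
                                    NaN),
             wt_frac_a1 = frac1, wt_frac_a2 = 1 - frac1)
}

#' Assign genes to allelic expression-change categories
#'
#' Implements the decision tree classifying knockout-downregulated genes:
#'
#' \enumerate{
#'   \item Monoallelic candidates pass the allele-specific gate
#'     (AS p < \code{as_p} and |AS log2FC| > \code{as_abs_lfc}) and a
#'     secondary downregulation filter (standard q < \code{standard_q} with
#'     negative standard log2FC, or either allele's p < \code{allelic_p}
#'     with that allele's log2FC negative).
#'   \item Mono-to-none gates are evaluated first: mono_A2_to_none requires
#'     a wild-type log2(a2/a1) ratio above +\code{wt_ratio_bound} and
#'     allele-2 log2FC < 0; mono_A1_to_none is the mirror.
#'   \item bi_to_mono_A2 (allele 1 silenced, allele 2 surviving) requires
#'     WT ratio > -\code{wt_ratio_bound}, WT allele-1 fraction >
#'     \code{wt_frac_min} and allele-1 log2FC < 0; bi_to_mono_A1 is the
#'     mirror. If both gates pass, the side with the more negative allelic
#'     log2FC is silenced.
#'   \item Genes downregulated non-allelically (standard q <
#'     \code{standard_q} with negative standard log2FC, or either allele
#'     p < \code{allelic_p} with that allele's log2FC negative) and not in a
#'     monoallelic category become bi_to_bi_down.
#'   \item The strict flag marks bi_to_mono genes whose silenced-allele
#'     log2FC is below \code{strict_lfc} (complete loss).
#' }
#'
#' Upregulated genes are never categorized. Genes with undefined wild-type
#' statistics are unclassified with a reason code.
#'
#' @param suite A \code{DESuiteResult}.
#' @param wt_stats Output of \code{\link{compute_wt_allele_stats}} on the
#'   same genes.
#' @param thresholds An \code{\link{ase_thresholds}}.
#' @return data.frame of class \code{CategoryCall}: gene_id, category,
#'   strict_bi_to_mono, silenced_allele, reason, plus the gate statistics.
#' @export
assign_categories <- function(suite, wt_stats, thresholds = ase_thresholds()) {
  stopifnot(inherits(suite, "DESuiteResult"),
            inherits(thresholds, "ase_thresholds"))
  if (!identical(suite$standard$gene_id, wt_stats$gene_id)) {
    wt_stats <- wt_stats[match(suite$standard$gene_id, wt_stats$gene_id), ]
    if (anyNA(wt_stats$gene_id)) stop("suite and wt_stats cover different genes")
  }
  th <- thresholds
  std <- suite$standard; a1 <- suite$allele1; a2 <- suite$allele2
  as_ <- suite$allele_specific
  ng <- nrow(std)

  ok <- function(x) !is.na(x)
  as_gate <- ok(as_$p) & as_$p < th$as_p & abs(as_$log2FC) > th$as_abs_lfc
  # secondary filter: downregulation evidence in at least one other mode
  secondary <- (ok(std$q) & std$q < th$standard_q & std$log2FC < 0) |
    (ok(a1$p) & a1$p < th$allelic_p & a1$log2FC < 0) |
    (ok(a2$p) & a2$p < th$allelic_p & a2$log2FC < 0)
  candidate <- as_gate & secondary
  ratio <- wt_stats$wt_log2_ratio
  stats_ok <- is.finite(ratio)

  mono_a2 <- candidate & stats_ok & ratio > th$wt_ratio_bound &
    ok(a2$log2FC) & a2$log2FC < 0
  mono_a1 <- candidate & stats_ok & ratio < -th$wt_ratio_bound &
    ok(a1$log2FC) & a1$log2FC < 0
  bi_a2 <- candidate & stats_ok & ratio > -th$wt_ratio_bound &
    wt_stats$wt_frac_a1 > th$wt_frac_min & ok(a1$log2FC) & a1$log2FC < 0
  bi_a1 <- candidate & stats_ok & ratio < th$wt_ratio_bound &
    wt_stats$wt_frac_a2 > th$wt_frac_min & ok(a2$log2FC) & a2$log2FC < 0

  category <- rep("unclassified", ng)
  silenced <- rep(NA_character_, ng)
  reason <- rep(NA_character_, ng)

  # mono-to-none first: the WT ratio bounds keep them disjoint from bi gates
  category[mono_a2] <- "mono_A2_to_none"; silenced[mono_a2] <- "a2"
  category[mono_a1] <- "mono_A1_to_none"; silenced[mono_a1] <- "a1"
  open <- category == "unclassified"
  both <- open & bi_a1 & bi_a2
  # conflict rule: silence the side with the more negative allelic log2FC
  a1_worse <- ok(a1$log2FC) & ok(a2$log2FC) & a1$log2FC <= a2$log2FC
  take_a2 <- open & ((bi_a2 & !bi_a1) | (both & a1_worse))
  take_a1 <- open & ((bi_a1 & !bi_a2) | (both & !a1_worse))
  category[take_a2] <- "bi_to_mono_A2"; silenced[take_a2] <- "a1"
  category[take_a1] <- "bi_to_mono_A1"; silenced[take_a1] <- "a2"

  down_nonallelic <- (ok(std$q) & std$q < th$standard_q & std$log2FC < 0) |
    (ok(a1$p) & a1$p < th$allelic_p & a1$log2FC < 0) |
    (ok(a2$p) & a2$p < th$allelic_p & a2$log2FC < 0)
  bdown <- category == "unclassified" & down_nonallelic & stats_ok
  category[bdown] <- "bi_to_bi_down"

  strict <- rep(FALSE, ng)
  is_bm <- category %in% c("bi_to_mono_A1", "bi_to_mono_A2")
  sil_lfc <- ifelse(silenced == "a1", a1$log2FC, a2$log2FC)
  strict[is_bm] <- !is.na(sil_lfc[is_bm]) & sil_lfc[is_bm] < th$strict_lfc

  reason[!stats_ok] <- "undefined_wt_stats"
  reason[!std$tested] <- "not_tested"

  out <- data.frame(gene_id = std$gene_id, category = category,
                    strict_bi_to_mono = strict, silenced_allele = silenced,
                    reason = reason,
                    as_p = as_$p, as_log2FC = as_$log2FC,
                    standard_q = std$q, standard_log2FC = std$log2FC,
                    allele1_p = a1$p, allele1_log2FC = a1$log2FC,
                    allele2_p = a2$p, allele2_log2FC = a2$log2FC,
                    wt_log2_ratio = ratio, wt_frac_a1 = wt_stats$wt_frac_a1)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("CategoryCall", "data.frame")
  out
}

#' Select a seeded random control gene set
#'
#' Draws \code{n_controls} genes uniformly without replacement from the pool
#' of genes showing no expression change after the knockout. Eligibility is
#' conservative: standard q > 0.5, |standard log2FC| < 0.1 and
#' allele-specific p > 0.5.
#'
#' @param suite A \code{DESuiteResult}.
#' @param thresholds An \code{\link{ase_thresholds}} (for n_controls).
#' @param seed Integer seed.
#' @return Character vector of control gene ids.
#' @export
select_controls <- function(suite, thresholds = ase_thresholds(), seed = 1L) {
  stopifnot(inherits(suite, "DESuiteResult"))
  std <- suite$standard; as_ <- suite$allele_specific
  pool <- std$gene_id[!is.na(std$q) & std$q > 0.5 &
                        abs(std$log2FC) < 0.1 &
                        !is.na(as_$p) & as_$p > 0.5]
  n <- thresholds$n_controls
  if (length(pool) < n) {
    stop("control pool too small: ", length(pool), " eligible, ", n,
         " requested")
  }
  set.seed(seed)
  sort(sample(pool, n))
}
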