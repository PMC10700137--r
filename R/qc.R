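#' Allelic chromosome copy-number flags from coverage CPM
#'
#' Normalizes each allele's per-chromosome read counts to counts per million
#' over that allele's genome total and flags chromosomes whose allele-2 /
#' allele-1 CPM ratio falls outside the open interval (low, high) — the
#' signature of an allelic copy-number difference. A genome-wide uniform
#' allelic imbalance is invisible by construction, since CPM normalizes each
#' allele's total to one million.
#'
#' @param coverage data.frame with columns chrom, allele ("a1"/"a2"),
#'   count.
#' @param low,high Ratio bounds (defaults 0.8 and 1.2, strict inequalities).
#' @return data.frame per chromosome: cpm_a1, cpm_a2, ratio, flagged.
#' @export
chromosome_cpm_flags <- function(coverage, low = 0.8, high = 1.2) {
  stopifnot(all(coverage$allele %in% c("a1", "a2")), all(coverage$count >= 0))
  tot <- tapply(coverage$count, coverage$allele, sum)
  if (any(is.na(tot[c("a1", "a2")])) || any(tot[c("a1", "a2")] == 0)) {
    stop("both alleles need nonzero genome-wide totals")
  }
  chroms <- sort(unique(coverage$chrom))
  get <- function(al) {
    x <- coverage[coverage$allele == al, ]
    cnt <- stats::setNames(rep(0, length(chroms)), chroms)
    cnt[x$chrom] <- x$count
    1e6 * cnt / tot[[al]]
  }
  cpm1 <- get("a1"); cpm2 <- get("a2")
  ratio <- ifelse(cpm1 == 0, Inf, cpm2 / cpm1)
  data.frame(chrom = chroms, cpm_a1 = unname(cpm1), cpm_a2 = unname(cpm2),
             ratio = unname(ratio),
             flagged = unname(ratio < low | ratio > high))
}

#' RNA-based allelic copy-number flags from biased-gene counts
#'
#' For clones without genomic coverage data: per chromosome, counts genes
#' biased toward each allele (from a within-condition allele-2 versus
#' allele-1 test; biased = p below \code{p_cut} and |log2FC| above
#' \code{lfc_cut}) and flags chromosomes where
#' |log2((n_a2 + pc) / (n_a1 + pc))| exceeds 1.
#'
#' @param allele_bias data.frame per gene: chrom, p, log2FC (allele 2 vs
#'   allele 1).
#' @param pseudocount Added to both biased-gene counts (default 1).
#' @param p_cut,lfc_cut Biased-gene criteria (defaults 0.01 and 0.5).
#' @param flag_abs_log2 Flag threshold on |L| (default 1).
#' @return data.frame per chromosome: n_tested, n_a1_biased, n_a2_biased,
#'   log2_bias_ratio, flagged. Chromosomes with no tested genes are skipped
#'   with a warning.
#' @export
rna_copy_number_flags <- function(allele_bias, pseudocount = 1,
                                  p_cut = 0.01, lfc_cut = 0.5,
                                  flag_abs_log2 = 1) {
  chroms <- sort(unique(allele_bias$chrom))
  rows <- list()
  for (ch in chroms) {
    x <- allele_bias[allele_bias$chrom == ch, ]
    tested <- !is.na(x$p)
    if (!any(tested)) {
      warning("chromosome ", ch, " has no tested genes; skipped")
      next
    }
    biased <- tested & x$p < p_cut & abs(x$log2FC) > lfc_cut
    n2 <- sum(biased & x$log2FC > 0)
    n1 <- sum(biased & x$log2FC < 0)
    L <- log2((n2 + pseudocount) / (n1 + pseudocount))
    rows[[ch]] <- data.frame(chrom = ch, n_tested = sum(tested),
                             n_a1_biased = n1, n_a2_biased = n2,
                             log2_bias_ratio = L,
                             flagged = abs(L) > flag_abs_log2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-condition allele-2 versus allele-1 differential test
#'
#' Convenience wrapper producing the per-gene allele-bias statistics that
#' \code{\link{rna_copy_number_flags}} consumes: an NB GLM on the
#' sample-by-allele layout of one condition with design ~ allele.
#'
#' @param table An \code{AlleleCountTable}.
#' @param condition "WT" (default) or "KO".
#' @param annotation Optional data.frame gene_id, chrom to attach.
#' @return data.frame per gene: gene_id, chrom (if supplied), log2FC
#'   (allele 2 vs allele 1), p.
#' @export
allele_bias_test <- function(table, condition = "WT", annotation = NULL) {
  stopifnot(inherits(table, "AlleleCountTable"))
  keep <- table$samples$condition == condition
  if (sum(keep) < 2L) stop("need >= 2 samples in the condition")
  counts <- cbind(table$a1[, keep, drop = FALSE],
                  table$a2[, keep, drop = FALSE])
  al2 <- rep(c(0, 1), each = sum(keep))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, factor(al2))
  X <- cbind(intercept = 1, allele = al2)
  ng <- nrow(counts)
  lfc <- p <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    if (disp$untestable[g]) next
    f <- fit_nb_glm_wald(counts[g, ], X, sf, disp$alpha[g])
    lfc[g] <- f$log2fc["allele"]; p[g] <- f$p["allele"]
  }
  out <- data.frame(gene_id = table$gene_id, log2FC = lfc, p = p)
  if (!is.null(annotation)) {
    out$chrom <- annotation$chrom[match(out$gene_id, annotation$gene_id)]
  }
  out
}

#' Detection-based single-cell allele frequency
#'
#' The allele frequency of a gene is the number of cells detecting allele 1
#' divided by the number of cells detecting allele 1 or allele 2 (set
#' union, so cells detecting both count once). Genes detected in fewer than
#' \code{min_cells} cells are undefined.
#'
#' @param cells A \code{CellAlleleExpression} (matrices \code{a1},
#'   \code{a2}, cells x genes, counts >= 0).
#' @param gene Gene id (column name) or index.
#' @param min_cells Minimum cells detecting either allele (default 10).
#' @return list: af (NA when undefined), n_a1, n_a2, n_union, reason.
#' @export
cell_allele_frequency <- function(cells, gene, min_cells = 10L) {
  stopifnot(inherits(cells, "CellAlleleExpression"))
  d1 <- cells$a1[, gene] >= 1L
  d2 <- cells$a2[, gene] >= 1L
  n_union <- sum(d1 | d2)
  if (n_union < min_cells) {
    return(list(af = NA_real_, n_a1 = sum(d1), n_a2 = sum(d2),
                n_union = n_union, reason = "below_min_cells"))
  }
  list(af = sum(d1) / n_union, n_a1 = sum(d1), n_a2 = sum(d2),
       n_union = n_union, reason = NA_character_)
}
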