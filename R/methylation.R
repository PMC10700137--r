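#' Per-CpG methylation frequency
#'
#' The frequency is methylated reads over total reads at the CpG; CpGs with
#' zero coverage get NA and an \code{undefined} flag.
#'
#' @param table data.frame with columns count_M and count_U (a CpG
#'   methylation table; other columns are carried through).
#' @return The input with added \code{coverage}, \code{frequency},
#'   \code{undefined}.
#' @export
methylation_frequency <- function(table) {
  if (any(table$count_M < 0) || any(table$count_U < 0)) {
    stop("methylation counts must be non-negative")
  }
  cov <- table$count_M + table$count_U
  table$coverage <- cov
  table$frequency <- ifelse(cov > 0, table$count_M / cov, NA_real_)
  table$undefined <- cov == 0
  table
}

#' Call differentially methylated loci between two conditions
#'
#' CpGs are matched on (chrom, pos, allele), replicate counts pooled per
#' condition, and each CpG tested with the exact two-sided test on the 2x2
#' table of methylated/unmethylated reads in the two conditions, followed by
#' BH adjustment across tested CpGs. CpGs below the coverage floor in either
#' condition are excluded.
#'
#' @param wt_table,ko_table CpG methylation tables (chrom, pos, allele,
#'   count_M, count_U); replicate rows per CpG are allowed and pooled.
#' @param min_coverage Minimum pooled coverage per condition (default 10).
#' @param fdr DML threshold on q (default 1e-5).
#' @return data.frame of class \code{DMLResult}: chrom, pos, allele,
#'   frequencies and coverages per condition, delta_f (KO - WT), p, q,
#'   is_dml.
#' @export
call_dml <- function(wt_table, ko_table, min_coverage = 10L, fdr = 1e-5) {
  pool <- function(tab) {
    key <- paste(tab$chrom, tab$pos, tab$allele, sep = "\r")
    m <- rowsum(tab$count_M, key)
    u <- rowsum(tab$count_U, key)
    out <- data.frame(key = rownames(m), M = m[, 1L], U = u[, 1L])
    rownames(out) <- NULL
    out
  }
  wt <- pool(wt_table); ko <- pool(ko_table)
  shared <- intersect(wt$key, ko$key)
  if (!length(shared)) stop("no overlapping CpGs between conditions")
  wt <- wt[match(shared, wt$key), ]; ko <- ko[match(shared, ko$key), ]
  cov_wt <- wt$M + wt$U; cov_ko <- ko$M + ko$U
  keep <- cov_wt >= min_coverage & cov_ko >= min_coverage
  p <- rep(NA_real_, length(shared))
  for (i in which(keep)) {
    p[i] <- stats::fisher.test(matrix(c(wt$M[i], wt$U[i], ko$M[i], ko$U[i]),
                                      2L, 2L))$p.value
  }
  p <- pmin(p, 1)  # guard against fisher.test rounding above 1
  q <- adjust_bh(p)
  parts <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
                    allele = parts[, 3L],
                    f_wt = ifelse(cov_wt > 0, wt$M / cov_wt, NA_real_),
                    f_ko = ifelse(cov_ko > 0, ko$M / cov_ko, NA_real_),
                    coverage_wt = cov_wt, coverage_ko = cov_ko,
                    tested = keep, p = p, q = q,
                    is_dml = !is.na(q) & q < fdr)
  out$delta_f <- out$f_ko - out$f_wt
  out <- out[order(out$chrom, out$pos, out$allele), ]
  rownames(out) <- NULL
  class(out) <- c("DMLResult", "data.frame")
  out
}

#' Classify promoter methylation regions by frequency band
#'
#' Segments covered CpGs into regions of consecutive same-band CpGs (gap at
#' most \code{merge_gap}), where the bands are fully methylated (> 0.95),
#' low methylated (0.10 to 0.50) and unmethylated (< 0.10), then keeps
#' regions of length 350 to 2000 bp that overlap a TSS window (TSS +/- 100
#' bp, strand-aware TSS supplied by the caller).
#'
#' @param freqs data.frame with chrom, pos, frequency, coverage (e.g. from
#'   \code{\link{methylation_frequency}}); only CpGs with coverage >
#'   \code{min_coverage} are used.
#' @param tss data.frame with chrom and tss positions.
#' @param merge_gap Maximum gap between CpGs in one region (default 200 bp).
#' @param min_coverage Coverage floor, exclusive (default 10).
#' @param size_range Retained region lengths in bp (default c(350, 2000)).
#' @param tss_window Half-width of the TSS window (default 100 bp).
#' @return data.frame: chrom, start, end (0-based half-open), n_cpg, class
#'   ("fully", "low", "un"), mean_frequency.
#' @export
classify_methylation_regions <- function(freqs, tss, merge_gap = 200L,
                                         min_coverage = 10L,
                                         size_range = c(350L, 2000L),
                                         tss_window = 100L) {
  if (!nrow(freqs)) return(.empty_regions())
  freqs <- freqs[!is.na(freqs$frequency) & freqs$coverage > min_coverage, ]
  band <- function(f) {
    ifelse(f > 0.95, "fully", ifelse(f >= 0.10 & f <= 0.50, "low",
                                     ifelse(f < 0.10, "un", NA_character_)))
  }
  freqs$band <- band(freqs$frequency)
  freqs <- freqs[!is.na(freqs$band), ]
  if (!nrow(freqs)) return(.empty_regions())
  freqs <- freqs[order(freqs$chrom, freqs$pos), ]
  new_region <- c(TRUE, freqs$chrom[-1L] != freqs$chrom[-nrow(freqs)] |
                    freqs$band[-1L] != freqs$band[-nrow(freqs)] |
                    diff(freqs$pos) > merge_gap)
  rid <- cumsum(new_region)
  regions <- do.call(rbind, lapply(split(freqs, rid), function(rg) {
    data.frame(chrom = rg$chrom[1L], start = min(rg$pos),
               end = max(rg$pos) + 1L, n_cpg = nrow(rg),
               class = rg$band[1L], mean_frequency = mean(rg$frequency))
  }))
  len <- regions$end - regions$start
  regions <- regions[len >= size_range[1L] & len <= size_range[2L], ]
  if (!nrow(regions)) return(.empty_regions())
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(tss$tss - tss_window + 1L,
                                                    tss$tss + tss_window + 1L))
  hit <- GenomicRanges::countOverlaps(reg_gr, tss_gr) > 0L
  out <- regions[hit, ]
  rownames(out) <- NULL
  out
}

.empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_cpg = integer(), class = character(),
             mean_frequency = numeric())
}

#' Anticorrelation of allelic TF binding and allelic methylation
#'
#' Selects peaks with allele-biased binding (|log2(a2/a1)| above
#' \code{lfc_min}) and CpGs with allele-biased methylation (|f_a2 - f_a1|
#' above \code{delta_min}), joins them by interval overlap, and scores each
#' pair as concordant anticorrelation when the binding bias and the
#' methylation bias point to opposite alleles.
#'
#' @param peaks data.frame: chrom, start, end (0-based half-open), lfc
#'   (log2 allele2/allele1 binding signal).
#' @param cpgs data.frame: chrom, pos, delta_f (f_a2 - f_a1).
#' @param lfc_min Peak bias threshold (default 1).
#' @param delta_min CpG bias threshold (default 0.25).
#' @return list: \code{pairs} (joined records with \code{concordant}),
#'   \code{fraction_concordant}, \code{n_peaks}, \code{n_cpgs}.
#' @export
tf_meth_anticorrelation <- function(peaks, cpgs, lfc_min = 1,
                                    delta_min = 0.25) {
  pk <- peaks[abs(peaks$lfc) > lfc_min, ]
  cg <- cpgs[abs(cpgs$delta_f) > delta_min, ]
  if (!nrow(pk) || !nrow(cg)) {
    return(list(pairs = data.frame(), fraction_concordant = NA_real_,
                n_peaks = nrow(pk), n_cpgs = nrow(cg)))
  }
  pk_gr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
  cg_gr <- GenomicRanges::GRanges(cg$chrom,
                                  IRanges::IRanges(cg$pos + 1L, cg$pos + 1L))
  ov <- GenomicRanges::findOverlaps(pk_gr, cg_gr)
  if (!length(ov)) {
    return(list(pairs = data.frame(), fraction_concordant = NA_real_,
                n_peaks = nrow(pk), n_cpgs = nrow(cg)))
  }
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  pairs <- data.frame(chrom = pk$chrom[i], peak_start = pk$start[i],
                      peak_end = pk$end[i], peak_lfc = pk$lfc[i],
                      cpg_pos = cg$pos[j], cpg_delta_f = cg$delta_f[j])
  pairs$concordant <- sign(pairs$peak_lfc) != sign(pairs$cpg_delta_f)
  list(pairs = pairs, fraction_concordant = mean(pairs$concordant),
       n_peaks = nrow(pk), n_cpgs = nrow(cg))
}
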