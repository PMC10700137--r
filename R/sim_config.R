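#' Cross description for a hybrid clone
#'
#' Describes one F1 hybrid clone: which strain is the mother, which the
#' father, the sex, and (for female clones with clonal X inactivation) which
#' allele carries the inactive X. Allele labels follow the strain convention
#' used throughout the package: \code{a1} is the reference strain (C57BL/6 or
#' 129S1), \code{a2} is CAST, independent of parental origin.
#'
#' @param clone_id Character clone label.
#' @param maternal_strain,paternal_strain Strain names (must differ).
#' @param sex "F" or "M".
#' @param xi_allele "a1", "a2" or "none"; must be "none" for male clones.
#' @return list of class \code{cross_info}.
#' @export
cross_info <- function(clone_id, maternal_strain, paternal_strain,
                       sex = c("F", "M"), xi_allele = "none") {
  sex <- match.arg(sex)
  if (identical(maternal_strain, paternal_strain)) {
    stop("maternal and paternal strains must differ")
  }
  if (!xi_allele %in% c("a1", "a2", "none")) stop("invalid xi_allele")
  if (sex == "M" && xi_allele != "none") {
    stop("xi_allele must be 'none' for male clones")
  }
  structure(list(clone_id = clone_id, maternal_strain = maternal_strain,
                 paternal_strain = paternal_strain, sex = sex,
                 xi_allele = xi_allele),
            class = "cross_info")
}

#' Which allele is maternal in a clone
#'
#' Under the strain convention (a2 = CAST), the maternal allele is a2 exactly
#' when the mother is the CAST strain.
#'
#' @param cross A \code{cross_info}.
#' @return "a1" or "a2".
#' @export
maternal_allele <- function(cross) {
  if (identical(cross$maternal_strain, "CAST")) "a2" else "a1"
}

.sim_categories <- c("control", "bi_to_bi_down", "bi_to_mono_A1",
                     "bi_to_mono_A2", "mono_A1_to_none", "mono_A2_to_none",
                     "bi_to_mono_imprinted_maternal",
                     "bi_to_mono_imprinted_paternal",
                     "bi_to_mono_random", "escapee", "escapee_msl2_regulated")

#' Configuration for the synthetic hybrid experiment
#'
#' Defines the conditions the generator emulates: a knockout-versus-wild-type
#' contrast in F1 hybrid clones with allele-resolved NB counts, planted
#' allelic effects, SNP-assignment loss, and replicate structure. Defaults
#' mirror the hybrid NPC study design: six replicates per condition, NB
#' dispersion 0.05, complete-silencing log2 fold change of -3 for the
#' monoallelic transitions and -0.7 for biallelic downregulation, and a
#' reciprocal pair of female clones with opposite X inactivation.
#'
#' @param n_genes_per_category Named integer vector of planted gene counts;
#'   recognized names are listed in Details. Unnamed categories default to 0.
#' @param n_replicates Replicates per condition per clone (default 6).
#' @param base_mean Expected total expression per gene (normalized counts,
#'   default 500).
#' @param dispersion NB dispersion alpha, variance = mu + alpha mu^2
#'   (default 0.05), shared across alleles of a gene.
#' @param silencing_lfc Planted allelic log2FC for complete silencing
#'   (default -3).
#' @param down_lfc Planted per-allele log2FC for bi-to-bi-down genes
#'   (default -0.7).
#' @param assign_rate Fraction of a gene's reads assignable to an allele via
#'   strain SNPs (default 0.25); the remainder becomes unassigned reads so
#'   allelic counts sum to less than totals.
#' @param library_size_factors Per-sample depth multipliers (recycled over
#'   the samples of each clone); default all 1.
#' @param crosses List of \code{cross_info}; default a reciprocal pair of
#'   female clones ("CaBl": CAST mother, Xi on a2; "9sCa": CAST father, Xi
#'   on a1).
#' @param mono_minor_frac WT expressed fraction of the near-silent allele of
#'   monoallelic genes (default 0.02).
#' @param seed Integer seed; each gene draws from its own derived substream
#'   so extending the gene list does not perturb earlier genes.
#' @details Category names: control, bi_to_bi_down, bi_to_mono_A1,
#'   bi_to_mono_A2 (the surviving allele names the subclass, so
#'   bi_to_mono_A2 silences a1), mono_A1_to_none, mono_A2_to_none,
#'   bi_to_mono_imprinted_maternal / _paternal (lost allele tracks parental
#'   origin, so the silenced strain allele flips between reciprocal
#'   crosses), bi_to_mono_random (lost allele drawn per clone), escapee and
#'   escapee_msl2_regulated (X-linked, biallelic in females via partial
#'   escape from X inactivation; the msl2-regulated ones lose the Xi copy
#'   in the knockout).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes_per_category = NULL,
                       n_replicates = 6L,
                       base_mean = 500,
                       dispersion = 0.05,
                       silencing_lfc = -3,
                       down_lfc = -0.7,
                       assign_rate = 0.25,
                       library_size_factors = NULL,
                       crosses = NULL,
                       mono_minor_frac = 0.02,
                       seed = 1L) {
  default_n <- c(control = 300L, bi_to_bi_down = 300L, bi_to_mono_A1 = 300L,
                 bi_to_mono_A2 = 300L, mono_A1_to_none = 300L,
                 mono_A2_to_none = 300L,
                 bi_to_mono_imprinted_maternal = 50L,
                 bi_to_mono_imprinted_paternal = 50L,
                 bi_to_mono_random = 100L,
                 escapee = 100L, escapee_msl2_regulated = 100L)
  n <- default_n
  if (!is.null(n_genes_per_category)) {
    bad <- setdiff(names(n_genes_per_category), .sim_categories)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    n[] <- 0L
    n[names(n_genes_per_category)] <- as.integer(n_genes_per_category)
  }
  if (is.null(crosses)) {
    crosses <- list(
      cross_info("CaBl", "CAST", "BL6", sex = "F", xi_allele = "a2"),
      cross_info("9sCa", "129S1", "CAST", sex = "F", xi_allele = "a1"))
  }
  stopifnot(n_replicates >= 2L, dispersion >= 0,
            assign_rate > 0, assign_rate <= 1,
            silencing_lfc <= down_lfc, down_lfc <= 0,
            mono_minor_frac > 0, mono_minor_frac < 0.5)
  if (base_mean <= 0) stop("base_mean must be positive")
  for (cr in crosses) {
    if (!inherits(cr, "cross_info")) stop("crosses must be cross_info objects")
  }
  if (any(n[c("escapee", "escapee_msl2_regulated")] > 0) &&
      !any(vapply(crosses, function(cr) cr$xi_allele != "none", logical(1)))) {
    stop("escapee genes need at least one female clone with xi_allele set")
  }
  structure(list(n_genes_per_category = n, n_replicates = as.integer(n_replicates),
                 base_mean = base_mean, dispersion = dispersion,
                 silencing_lfc = silencing_lfc, down_lfc = down_lfc,
                 assign_rate = assign_rate,
                 library_size_factors = library_size_factors,
                 crosses = crosses, mono_minor_frac = mono_minor_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}
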