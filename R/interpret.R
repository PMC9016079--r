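#' Genotype (dosage) correlation between two SNPs in the whole sample
#'
#' Pearson correlation of the 0/1/2 allele-dosage vectors, the population
#' level LD summary plotted against the double-heterozygote allelic
#' correlation when interpreting significant associations.
#'
#' @param dosage1,dosage2 integer dosage vectors of equal length (>= 2).
#' @return Pearson r, or `NA` (with a warning) when either dosage has zero
#'   variance.
#' @export
genotype_correlation <- function(dosage1, dosage2) {
  if (length(dosage1) != length(dosage2) || length(dosage1) < 2L)
    stop("need two dosage vectors of equal length >= 2")
  if (stats::var(dosage1) == 0 || stats::var(dosage2) == 0) {
    warning("zero variance in a dosage vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(dosage1, dosage2)
}

#' Allelic correlation within double-heterozygous subjects
#'
#' Across the `2 n` phased chromosomes of the double-heterozygous subjects,
#' correlates the indicator of carrying the GWAS effect allele A with the
#' indicator of carrying the exonic allele B. Because each double
#' heterozygote carries exactly one A and one B, this conditional
#' correlation can reach |r| = 1 even when the two SNPs are in no
#' population-level LD: if the minor-minor haplotype ab is absent, the only
#' possible phase is (A-b, a-B), giving complete (negative) allelic
#' correlation.
#'
#' @param haplotypes data frame of double-heterozygous subjects with 0/1
#'   columns `g1`, `g2` (GWAS effect-allele indicator on haplotypes 1, 2)
#'   and `e1`, `e2` (exonic B-allele indicator), as returned by
#'   [simulate_haplotypes()].
#' @return Pearson r over chromosomes, or `NA` when fewer than 2 double
#'   heterozygotes or zero variance.
#' @export
allelic_correlation_double_het <- function(haplotypes) {
  dh <- haplotypes[haplotypes$g1 + haplotypes$g2 == 1L &
                   haplotypes$e1 + haplotypes$e2 == 1L, , drop = FALSE]
  if (nrow(dh) < 2L) return(NA_real_)
  g <- c(dh$g1, dh$g2)
  e <- c(dh$e1, dh$e2)
  if (stats::var(g) == 0 || stats::var(e) == 0) return(NA_real_)
  stats::cor(g, e)
}

#' Classify a significant association into interpretation categories
#'
#' Three-way interpretation of a significant (GWAS SNP, exonic SNP)
#' association:
#' \describe{
#'   \item{1}{the exonic SNP's p-value is less significant than the GWAS
#'     SNP's (`p_exonic > p_gwas`): the imbalance is unlikely to be
#'     mediated by the exonic proxy SNP itself;}
#'   \item{2}{otherwise, the two SNPs are in high LD (`|r| > 0.8`): the
#'     driving variant cannot be distinguished;}
#'   \item{3}{otherwise: the exonic SNP is the more likely driver, and the
#'     GWAS association may reflect inflated allelic correlation among the
#'     double heterozygotes.}
#' }
#' Ties (`p_exonic == p_gwas`) fall through to the LD branch, since
#' category 1 requires strictly less significance.
#'
#' @param p_gwas,p_exonic raw association p-values of the GWAS and exonic
#'   SNP (vectors recycle).
#' @param r_genotype whole-sample genotype correlation between the SNPs.
#' @param ld_threshold |r| above which the SNPs count as high-LD
#'   (default 0.8).
#' @return Integer vector of categories (1, 2, 3); `NA` where `p_exonic`
#'   is missing.
#' @export
classify_category <- function(p_gwas, p_exonic, r_genotype,
                              ld_threshold = 0.8) {
  n <- max(length(p_gwas), length(p_exonic), length(r_genotype))
  p_gwas <- rep_len(p_gwas, n)
  p_exonic <- rep_len(p_exonic, n)
  r_genotype <- rep_len(r_genotype, n)
  bad <- !is.na(p_gwas) & (p_gwas <= 0 | p_gwas > 1)
  if (any(bad, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  ifelse(is.na(p_exonic), NA_integer_,
    ifelse(p_exonic > p_gwas, 1L,
      ifelse(abs(r_genotype) > ld_threshold, 2L, 3L)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; significance in the
#' association tables is defined as adjusted p < 0.05 within each analysis
#' set (tissue or cell type).
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (same length and order).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Annotate an association table with LD summaries and categories
#'
#' Appends `fdr_p` (per-table BH adjustment), and for rows significant at
#' `fdr_threshold` the interpretation `category` from
#' [classify_category()]; non-significant rows get `NA`.
#'
#' @param assoc data frame with columns `p`, `p_exonic`, `r_genotype` (see
#'   [write_summary_stats()] for the full record layout).
#' @param fdr_threshold adjusted-p significance cutoff (default 0.05).
#' @return `assoc` with `fdr_p` and `category` columns filled.
#' @export
classify_associations <- function(assoc, fdr_threshold = 0.05) {
  assoc$fdr_p <- bh_fdr(assoc$p)
  sig <- !is.na(assoc$fdr_p) & assoc$fdr_p < fdr_threshold
  assoc$category <- NA_integer_
  if (any(sig))
    assoc$category[sig] <- classify_category(assoc$p[sig],
                                             assoc$p_exonic[sig],
                                             assoc$r_genotype[sig])
  assoc
}
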