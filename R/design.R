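#' Code a biallelic exonic genotype into allele patterns
#'
#' Maps the effect-allele dosage at a transcribed SNP onto the allele
#' patterns used by the hierarchical Poisson mixed model. A homozygous
#' subject contributes one pattern (`"AA"` with coding `X = 1`, or `"aa"`
#' with `X = 0`); a heterozygous subject is split into the two allelic
#' patterns `"A"` (`X = 1`) and `"a"` (`X = 0`), which enter the model as
#' paired observations.
#'
#' @param dosage integer 0, 1 or 2: copies of the effect allele.
#' @return A data frame with columns `pattern` and `X`.
#' @examples
#' code_exonic(2) # one row: pattern "AA", X = 1
#' code_exonic(1) # two rows: patterns "A" and "a"
#' @export
code_exonic <- function(dosage) {
  if (length(dosage) != 1L || is.na(dosage) || !dosage %in% 0:2)
    stop("'dosage' must be a single value in {0, 1, 2}; multiallelic or ",
         "missing genotypes cannot be coded")
  switch(as.character(dosage),
         "2" = data.frame(pattern = "AA", X = 1),
         "1" = data.frame(pattern = c("A", "a"), X = c(1, 0)),
         "0" = data.frame(pattern = "aa", X = 0))
}

#' Code a GWAS SNP through a phased exonic proxy SNP
#'
#' For a subject heterozygous at both the GWAS SNP (alleles A/a) and the
#' exonic SNP (alleles B/b) -- "double-heterozygous" -- phase determines
#' which exonic allele rides on each GWAS haplotype, so the subject is split
#' into two allelic observations: the haplotype carrying the GWAS effect
#' allele A contributes the read count of its phased exonic allele with
#' `X = 1`, the other haplotype contributes the remaining count with
#' `X = 0`, and each observation carries half the library size as offset.
#' Subjects that are not double-heterozygous contribute a single observation
#' holding the total exonic count, coded `X = 1, 0.5, 0` for GWAS genotypes
#' AA, Aa, aa, with the full library size as offset.
#'
#' @param gwas_dosage effect-allele dosage (0/1/2) at the GWAS SNP.
#' @param exonic_het logical: is the subject heterozygous at the exonic SNP?
#' @param phased logical: is phase known across the two loci? Required when
#'   double-heterozygous.
#' @param y_eff for double-heterozygous subjects, the count of the exonic
#'   allele phased with the GWAS effect allele; otherwise any allelic count
#'   summed into the total.
#' @param y_oth the count of the other exonic allele.
#' @param library_size subject library size \eqn{l_i} (or normalizing
#'   factor), > 0.
#' @return A data frame of observation rows with columns `pattern`, `y`,
#'   `X`, `K`.
#' @export
code_gwas_haplotype <- function(gwas_dosage, exonic_het, phased,
                                y_eff, y_oth, library_size) {
  if (!gwas_dosage %in% 0:2) stop("'gwas_dosage' must be 0, 1 or 2")
  if (library_size <= 0) stop("'library_size' must be positive")
  double_het <- gwas_dosage == 1L && isTRUE(exonic_het)
  if (double_het) {
    if (!isTRUE(phased))
      stop("phase required: double-heterozygous subjects cannot be coded ",
           "from unphased genotypes")
    data.frame(pattern = c("A", "a"), y = c(y_eff, y_oth),
               X = c(1, 0), K = library_size / 2)
  } else {
    pattern <- c("aa", "Aa", "AA")[gwas_dosage + 1L]
    data.frame(pattern = pattern, y = y_eff + y_oth,
               X = gwas_dosage / 2, K = library_size)
  }
}

#' Build the HPMM design from per-subject genotypes and allelic counts
#'
#' Converts a table of subjects into the observation-level design of the
#' hierarchical Poisson mixed model, in either of two modes:
#' \describe{
#'   \item{`"exonic"`}{the tested SNP is itself transcribed. `dosage` is the
#'     effect-allele dosage at the exonic SNP; heterozygous subjects are
#'     split into two allelic observations (`y_eff`, `y_oth`) with offset
#'     \eqn{l_i/2} each, homozygous subjects contribute their total count
#'     with offset \eqn{l_i}.}
#'   \item{`"gwas"`}{the tested SNP is non-transcribed and read through a
#'     phased exonic proxy SNP; see [code_gwas_haplotype()]. `dosage` is the
#'     effect-allele dosage at the GWAS SNP and the columns `exonic_het` and
#'     `phased` are required.}
#' }
#'
#' @param subjects data frame with columns `subject_id`, `dosage`, `y_eff`,
#'   `y_oth`, `library_size`, plus `exonic_het` and `phased` in GWAS mode.
#' @param mode `"exonic"` or `"gwas"`.
#' @param covariates optional data frame with `subject_id` plus covariate
#'   columns; subject-level values are replicated across a subject's two
#'   allelic observations.
#' @param group optional data frame with `subject_id` and a 0/1 column `D`
#'   (e.g. disease status) for the interaction model.
#' @param min_double_het analyses with fewer double-heterozygous (or, in
#'   exonic mode, heterozygous) subjects than this are flagged (default 3);
#'   they remain fittable on request.
#' @return An object of class `hpmm_design`: a data frame of observations
#'   (`subject_id`, `pattern`, `y`, `X`, `K`, covariates, `D`) with
#'   attributes `mode`, `n_double_het`, `flag_low_double_het`,
#'   `untestable` (no variation in `X`).
#' @export
build_design <- function(subjects, mode = c("exonic", "gwas"),
                         covariates = NULL, group = NULL,
                         min_double_het = 3) {
  mode <- match.arg(mode)
  req <- c("subject_id", "dosage", "y_eff", "y_oth", "library_size")
  if (mode == "gwas") req <- c(req, "exonic_het", "phased")
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols))
    stop("'subjects' lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(subjects) == 0L) stop("no subjects: the design would be empty")

  if (!all(subjects$dosage %in% 0:2))
    stop("'dosage' must be 0, 1 or 2 (biallelic effect-allele dosage)")
  if (any(subjects$library_size <= 0)) stop("library sizes must be positive")

  # vectorized equivalent of applying code_exonic() / code_gwas_haplotype()
  # subject by subject: split subjects contribute two allelic rows
  split <- if (mode == "exonic") subjects$dosage == 1L
           else subjects$dosage == 1L & subjects$exonic_het
  if (mode == "gwas" && any(split & !subjects$phased))
    stop("phase required: double-heterozygous subjects cannot be coded ",
         "from unphased genotypes")
  idx <- rep(seq_len(nrow(subjects)), times = ifelse(split, 2L, 1L))
  first <- !duplicated(idx)
  is_split <- split[idx]
  d <- subjects$dosage[idx]
  hom_pattern <- if (mode == "exonic") c("aa", NA, "AA")[d + 1L]
                 else c("aa", "Aa", "AA")[d + 1L]
  obs <- data.frame(
    subject_id = subjects$subject_id[idx],
    pattern = ifelse(is_split, ifelse(first, "A", "a"), hom_pattern),
    y = ifelse(is_split,
               ifelse(first, subjects$y_eff[idx], subjects$y_oth[idx]),
               subjects$y_eff[idx] + subjects$y_oth[idx]),
    X = ifelse(is_split, as.numeric(first), d / 2),
    K = subjects$library_size[idx] / ifelse(is_split, 2, 1))

  if (!is.null(covariates)) {
    idx <- match(obs$subject_id, covariates$subject_id)
    if (anyNA(idx)) stop("covariates missing for some subjects")
    for (v in setdiff(names(covariates), "subject_id"))
      obs[[v]] <- covariates[[v]][idx]
    attr(obs, "covariate_names") <- setdiff(names(covariates), "subject_id")
  }
  if (!is.null(group)) {
    idx <- match(obs$subject_id, group$subject_id)
    if (anyNA(idx)) stop("group labels missing for some subjects")
    if (!all(group$D %in% c(0, 1))) stop("group column 'D' must be 0/1")
    obs$D <- group$D[idx]
  }

  split_subjects <- sum(split)
  if (nrow(obs) == 0L) stop("zero observations in design")

  structure(obs,
            class = c("hpmm_design", "data.frame"),
            mode = mode,
            n_double_het = split_subjects,
            flag_low_double_het = split_subjects < min_double_het,
            min_double_het = min_double_het,
            untestable = stats::var(obs$X) == 0)
}

#' @export
print.hpmm_design <- function(x, ...) {
  cat(sprintf("HPMM design (%s mode): %d observations, %d subjects, %d %s\n",
              attr(x, "mode"), nrow(x), length(unique(x$subject_id)),
              attr(x, "n_double_het"),
              if (attr(x, "mode") == "gwas") "double-heterozygous"
              else "heterozygous (split)"))
  if (isTRUE(attr(x, "untestable")))
    cat("NOTE: no variation in X; the aseQTL effect is untestable\n")
  if (isTRUE(attr(x, "flag_low_double_het")))
    cat(sprintf("NOTE: fewer than %d split subjects\n",
                attr(x, "min_double_het")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
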