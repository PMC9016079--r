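#' Read phased genotypes from a VCF
#'
#' Extracts one record per subject x locus from the GT field of a VCF.
#' Phasing is taken from the GT separator (`|` phased, `/` unphased), and
#' the imputation quality is parsed from the INFO `R2` key when present; a
#' `TYPED` INFO flag (or absence of `R2`) marks the locus as directly
#' genotyped.
#'
#' @param path VCF file (plain text or bgzip).
#' @param loci_of_interest optional data frame with columns `chrom`, `pos`
#'   (1-based); loci absent from the file yield a warning and no records.
#' @return Data frame with columns `subject_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `allele1`, `allele2` (haplotype 1 and 2; `NA` when the call is
#'   missing), `phased`, `missing`, `imputation_r2`, `genotyped`.
#' @export
read_phased_vcf <- function(path, loci_of_interest = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(loci_of_interest)) {
    want <- paste(loci_of_interest$chrom, loci_of_interest$pos)
    have <- paste(fix$CHROM, pos)
    keep <- have %in% want
    absent <- setdiff(want, have)
    if (length(absent))
      warning("loci not found in VCF: ", paste(absent, collapse = ", "))
  }
  if (!any(keep))
    return(data.frame(subject_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), allele1 = character(0),
                      allele2 = character(0), phased = logical(0),
                      missing = logical(0), imputation_r2 = numeric(0),
                      genotyped = logical(0)))

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  info <- fix$INFO
  r2 <- rep(NA_real_, length(info))
  m <- regexpr("(^|;)R2=[0-9.eE+-]+", info)
  r2[m != -1L] <- suppressWarnings(as.numeric(
    sub("^;?R2=", "", regmatches(info, m))))
  typed <- grepl("(^|;)TYPED($|;)", info)

  records <- lapply(seq_len(nrow(fix)), function(v) {
    alleles <- c(fix$REF[v], strsplit(fix$ALT[v], ",", fixed = TRUE)[[1]])
    g <- gt[v, ]
    out <- data.frame(subject_id = colnames(gt), chrom = fix$CHROM[v],
                      pos = pos[v], ref = fix$REF[v], alt = fix$ALT[v],
                      allele1 = NA_character_, allele2 = NA_character_,
                      phased = FALSE, missing = FALSE,
                      imputation_r2 = r2[v],
                      genotyped = typed[v] || is.na(r2[v]),
                      stringsAsFactors = FALSE)
    miss <- is.na(g) | g %in% c(".", "./.", ".|.")
    out$missing <- miss
    parse <- g[!miss]
    subj <- colnames(gt)[!miss]
    if (length(parse)) {
      okfmt <- grepl("^[0-9]+[|/][0-9]+$", parse)
      if (any(!okfmt))
        stop(sprintf("malformed GT '%s' for subject %s at %s:%d",
                     parse[!okfmt][1], subj[!okfmt][1],
                     fix$CHROM[v], pos[v]))
      idx <- t(vapply(strsplit(parse, "[|/]"),
                      function(z) as.integer(z) + 1L, integer(2)))
      if (any(idx > length(alleles)))
        stop(sprintf("GT allele index out of range at %s:%d",
                     fix$CHROM[v], pos[v]))
      out$allele1[!miss] <- alleles[idx[, 1]]
      out$allele2[!miss] <- alleles[idx[, 2]]
      out$phased[!miss] <- grepl("|", parse, fixed = TRUE)
    }
    out
  })
  do.call(rbind, records)
}

#' Filter genotype records on imputation quality
#'
#' Keeps records whose imputation \eqn{R^2} strictly exceeds `r2_min`
#' (default 0.96) -- the filter exists to control phasing errors of imputed
#' calls, so directly genotyped records (missing \eqn{R^2} with
#' `genotyped = TRUE`) bypass it.
#'
#' @param records output of [read_phased_vcf()].
#' @param r2_min threshold in `[0, 1]`; strict inequality.
#' @return The retained records.
#' @export
filter_imputation_quality <- function(records, r2_min = 0.96) {
  stopifnot(r2_min >= 0, r2_min <= 1)
  keep <- ifelse(is.na(records$imputation_r2),
                 records$genotyped,
                 records$imputation_r2 > r2_min)
  records[keep, , drop = FALSE]
}

#' Check an imputed genotype against RNA-seq allelic counts
#'
#' Compares the imputed call with the allelic read counts at the locus.
#' With more than 20 overlapping reads, a homozygous call with an allelic
#' ratio (minor count / major count) above 10\%, or a heterozygous call
#' with a ratio below 2\%, is deemed inconsistent and overridden by the
#' RNA-seq-implied genotype (heterozygous when the ratio is at least 2\%,
#' homozygous for the major allele otherwise). With 20 or fewer reads the
#' imputed genotype is retained (`insufficient_depth`).
#'
#' @param imputed `"hom"` or `"het"`.
#' @param counts numeric vector of the two allele counts.
#' @return List with `status` (`"consistent"`, `"override_to_rnaseq_call"`
#'   or `"insufficient_depth"`), `genotype` (the genotype to use
#'   downstream), and `ratio`.
#' @export
genotype_consistency_check <- function(imputed = c("hom", "het"), counts) {
  imputed <- match.arg(imputed)
  if (length(counts) != 2L || any(counts < 0))
    stop("'counts' must be two non-negative allele counts")
  total <- sum(counts)
  ratio <- if (max(counts) == 0) 0 else min(counts) / max(counts)
  if (total <= 20)
    return(list(status = "insufficient_depth", genotype = imputed,
                ratio = ratio))
  inconsistent <- (imputed == "hom" && ratio > 0.10) ||
                  (imputed == "het" && ratio < 0.02)
  if (inconsistent) {
    list(status = "override_to_rnaseq_call",
         genotype = if (ratio >= 0.02) "het" else "hom", ratio = ratio)
  } else {
    list(status = "consistent", genotype = imputed, ratio = ratio)
  }
}

#' Drop exonic loci with low mean coverage
#'
#' A locus is retained only when the mean total count per subject (over all
#' subjects of the analysis set) is at least `min_mean`; loci barely
#' overlapped by reads lack power and are excluded.
#'
#' @param counts data frame with columns `subject_id`, `chrom`, `pos` and
#'   `count` (per-allele rows are summed within subject x locus).
#' @param min_mean exclusion threshold (default 2; exclusion is strict
#'   `mean < min_mean`).
#' @return Data frame of retained loci (`chrom`, `pos`, `mean_count`).
#' @export
filter_low_expression <- function(counts, min_mean = 2) {
  if (nrow(counts) == 0L || length(unique(counts$subject_id)) == 0L)
    stop("empty subject set")
  per_subj <- stats::aggregate(count ~ chrom + pos + subject_id,
                               data = counts, FUN = sum)
  n_subj <- length(unique(counts$subject_id))
  tot <- stats::aggregate(count ~ chrom + pos, data = per_subj, FUN = sum)
  tot$mean_count <- tot$count / n_subj
  keep <- tot$mean_count >= min_mean
  tot[keep, c("chrom", "pos", "mean_count"), drop = FALSE]
}

#' Pair GWAS SNPs with local genes and their exonic SNPs
#'
#' A gene enters the cis set of a GWAS SNP when its transcription start
#' site lies within +/- 500 kb of the SNP (inclusive, same chromosome);
#' every QC-passing exonic SNP of an included gene yields one
#' (GWAS SNP, gene, exonic SNP) triple.
#'
#' @param gwas_snps data frame: `snp_id`, `chrom`, `pos`.
#' @param genes data frame: `gene`, `chrom`, `tss`.
#' @param exonic_snps data frame: `gene`, `snp_id`, `chrom`, `pos`.
#' @param window half-width in bp (default `5e5`).
#' @return Data frame of triples `gwas_snp`, `gene`, `exonic_snp`.
#' @export
select_cis_pairs <- function(gwas_snps, genes, exonic_snps, window = 5e5) {
  out <- list()
  for (i in seq_len(nrow(gwas_snps))) {
    g <- genes[genes$chrom == gwas_snps$chrom[i] &
               abs(genes$tss - gwas_snps$pos[i]) <= window, , drop = FALSE]
    if (nrow(g) == 0L) next
    ex <- exonic_snps[exonic_snps$gene %in% g$gene, , drop = FALSE]
    if (nrow(ex) == 0L) next
    out[[length(out) + 1L]] <- data.frame(gwas_snp = gwas_snps$snp_id[i],
                                          gene = ex$gene,
                                          exonic_snp = ex$snp_id)
  }
  if (!length(out))
    return(data.frame(gwas_snp = character(0), gene = character(0),
                      exonic_snp = character(0)))
  do.call(rbind, out)
}

SUMMARY_COLS <- c("gwas_snp", "exonic_snp", "gene", "beta", "se", "p",
                  "fdr_p", "n_double_het", "r_genotype", "r_allelic",
                  "category")

#' Write / read the association summary-statistics table
#'
#' Tab-separated, fixed column order (`gwas_snp`, `exonic_snp`, `gene`,
#' `beta`, `se`, `p`, `fdr_p`, `n_double_het`, `r_genotype`, `r_allelic`,
#' `category`); numeric columns are serialized with 17 significant digits
#' so a write/read round trip is lossless.
#'
#' @param records data frame holding (at least) the summary columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  for (cn in setdiff(SUMMARY_COLS, names(records))) records[[cn]] <- NA
  records <- records[, SUMMARY_COLS, drop = FALSE]
  fmt <- records
  for (cn in names(fmt))
    if (is.double(fmt[[cn]]))
      fmt[[cn]] <- ifelse(is.na(fmt[[cn]]), "NA",
                          sprintf("%.17g", fmt[[cn]]))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(gwas_snp = "character",
                                   exonic_snp = "character",
                                   gene = "character",
                                   beta = "numeric", se = "numeric",
                                   p = "numeric", fdr_p = "numeric",
                                   n_double_het = "integer",
                                   r_genotype = "numeric",
                                   r_allelic = "numeric",
                                   category = "integer"))
}

#' Read an allelic-count TSV
#'
#' Expected columns: `subject_id`, `chrom`, `pos`, `allele`, `count`, and
#' optionally `library_size` and `cell_type`. When `library_size` is
#' absent it defaults to the subject's total summed count over all rows of
#' the table.
#'
#' @param path TSV path.
#' @return Data frame with a `library_size` column guaranteed.
#' @export
read_allelic_counts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  req <- c("subject_id", "chrom", "pos", "allele", "count")
  if (length(setdiff(req, names(x))))
    stop("allelic-count table lacks column(s): ",
         paste(setdiff(req, names(x)), collapse = ", "))
  if (is.null(x$library_size)) {
    tot <- tapply(x$count, x$subject_id, sum)
    x$library_size <- as.numeric(tot[as.character(x$subject_id)])
  }
  x
}
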