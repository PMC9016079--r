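#' Materialize a deterministic toy-data scenario
#'
#' Writes every input format the package consumes -- a phased VCF, an
#' allelic-count TSV, a covariate TSV, and for the UMI scenario a
#' read-level TSV -- together with a JSON manifest recording the ground
#' truth (true parameters, genotypes, counts). Regenerating a scenario
#' with the same seed reproduces byte-identical files; fixtures live as
#' generator code plus seeds, not as data files.
#'
#' Scenarios:
#' \describe{
#'   \item{`null_maf04`}{exonic-mode allelic counts under the null
#'     (\eqn{\beta = 0}), MAF 0.4, Var(b) = 1, Var(eps) = 0.5.}
#'   \item{`power_beta03`}{same layout with \eqn{\beta = 0.3}.}
#'   \item{`complete_allelic_corr`}{phased two-SNP genotypes built with a
#'     zero minor-minor haplotype frequency, so every double heterozygote
#'     is phased (A-b, a-B) and the allelic correlation is exactly -1
#'     while population LD is negligible.}
#'   \item{`umi_toy`}{hand-laid read-level snRNA-seq records exercising
#'     transcript filtering, conflicting-UMI removal, one-mismatch
#'     collapsing and per-cell UMI identity, with the expected pseudo-bulk
#'     counts in the manifest.}
#' }
#'
#' @param scenario scenario name (see Details).
#' @param dir output directory (created if needed; existing scenario files
#'   are an error).
#' @param n number of subjects for the simulated scenarios (default 200).
#' @param seed integer seed (default 42).
#' @return The manifest (also written to `<scenario>_manifest.json`),
#'   invisibly, with a `files` element of written paths.
#' @export
make_fixture <- function(scenario = c("null_maf04", "power_beta03",
                                      "complete_allelic_corr", "umi_toy"),
                         dir, n = 200, seed = 42) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, scenario)
  files <- paste0(prefix, c("_genotypes.vcf", "_counts.tsv",
                            "_covariates.tsv", "_reads.tsv",
                            "_manifest.json"))
  if (any(file.exists(files[c(1, 2, 5)])))
    stop("fixture files for '", scenario, "' already exist in ", dir)

  manifest <- switch(scenario,
    null_maf04 = fixture_exonic(prefix, n, seed, beta = 0, maf = 0.4),
    power_beta03 = fixture_exonic(prefix, n, seed, beta = 0.3, maf = 0.4),
    complete_allelic_corr = fixture_allelic_corr(prefix, n, seed),
    umi_toy = fixture_umi(prefix))
  manifest$scenario <- scenario
  manifest$seed <- seed
  jsonlite::write_json(manifest[setdiff(names(manifest), "files")],
                       paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- c(manifest$files, paste0(prefix, "_manifest.json"))
  invisible(manifest)
}

#' List available fixture scenarios
#' @return Character vector of scenario names.
#' @export
fixture_scenarios <- function() {
  c("null_maf04", "power_beta03", "complete_allelic_corr", "umi_toy")
}

write_fixture_vcf <- function(path, chrom, pos, ref, alt, gt_matrix,
                              subject_ids, r2 = 0.99) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", subject_ids), collapse = "\t")), con)
  for (v in seq_along(pos)) {
    writeLines(paste(c(chrom[v], pos[v], ".", ref[v], alt[v], ".", "PASS",
                       sprintf("R2=%.2f", r2), "GT", gt_matrix[v, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

fixture_exonic <- function(prefix, n, seed, beta, maf,
                           var_b = 1, var_eps = 0.5, mu = log(1e-4),
                           library_size = 1e6) {
  set.seed(seed)
  dosage <- simulate_genotypes(n, maf)
  subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         dosage = dosage, y_eff = 0L, y_oth = 0L,
                         library_size = library_size)
  design <- build_design(subjects, mode = "exonic")
  design <- simulate_counts(design, mu, beta, var_b, var_eps)

  # effect allele = REF (C), other allele = ALT (T); hets phased REF first
  gt <- vapply(dosage, function(d)
    c("1|1", "0|1", "0|0")[d + 1L], character(1))
  vcf_path <- paste0(prefix, "_genotypes.vcf")
  write_fixture_vcf(vcf_path, "chr1", 10177L, "C", "T",
                    matrix(gt, nrow = 1), subjects$subject_id)

  # one row per subject x allele; homozygotes put all reads on one allele
  rows <- lapply(seq_len(n), function(i) {
    sid <- subjects$subject_id[i]
    ys <- design$y[design$subject_id == sid]
    if (dosage[i] == 1L) {
      data.frame(subject_id = sid, chrom = "chr1", pos = 10177L,
                 allele = c("C", "T"), count = ys,
                 library_size = library_size)
    } else {
      data.frame(subject_id = sid, chrom = "chr1", pos = 10177L,
                 allele = if (dosage[i] == 2L) "C" else "T", count = ys,
                 library_size = library_size)
    }
  })
  counts <- do.call(rbind, rows)
  counts_path <- paste0(prefix, "_counts.tsv")
  utils::write.table(counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cov <- data.frame(subject_id = subjects$subject_id,
                    age = round(stats::rnorm(n, 80, 8), 1))
  cov_path <- paste0(prefix, "_covariates.tsv")
  utils::write.table(cov, cov_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(n = n, beta = beta, maf = maf, var_b = var_b, var_eps = var_eps,
       mu = mu, library_size = library_size,
       effect_allele = "C", dosage = dosage, y = design$y,
       subject_of_y = design$subject_id, X_of_y = design$X,
       files = c(vcf_path, counts_path, cov_path))
}

fixture_allelic_corr <- function(prefix, n, seed,
                                 maf_gwas = 0.05, maf_exonic = 0.05) {
  # ld_r chosen so the minor-minor haplotype frequency is exactly zero
  pa <- maf_gwas; pb <- maf_exonic
  ld_r <- -pa * pb / sqrt(pa * (1 - pa) * pb * (1 - pb))
  hap <- simulate_haplotypes(n, pa, pb, ld_r, seed = seed)

  gt <- rbind(paste0(1L - hap$g1, "|", 1L - hap$g2),   # 1 = minor allele a
              paste0(1L - hap$e1, "|", 1L - hap$e2))
  vcf_path <- paste0(prefix, "_genotypes.vcf")
  write_fixture_vcf(vcf_path, c("chr1", "chr1"), c(5000L, 9000L),
                    c("A", "G"), c("T", "C"), gt, hap$subject_id)
  n_dh <- sum(hap$gwas_dosage == 1L & hap$exonic_dosage == 1L)
  list(n = n, maf_gwas = pa, maf_exonic = pb, ld_r = ld_r,
       n_double_het = n_dh,
       r_allelic = allelic_correlation_double_het(hap),
       r_genotype = genotype_correlation(hap$gwas_dosage,
                                         hap$exonic_dosage),
       haplotypes = hap, files = vcf_path)
}

fixture_umi <- function(prefix) {
  reads <- data.frame(
    cell_barcode = c(rep("CELL1", 7), rep("CELL2", 3)),
    umi = c("AAAA", "AAAA", "AAAA", "AAAT", "CCCC", "CCCC", "GGGG",
            "AAAA", "TTTT", "TTTA"),
    chrom = "chr1", pos = 10177L,
    allele = c("C", "C", "C", "C", "C", "T", "T",
               "T", "C", "G"),
    n_reads = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L),
    transcript_assigned = c(rep(TRUE, 6), FALSE, TRUE, TRUE, TRUE))
  reads_path <- paste0(prefix, "_reads.tsv")
  utils::write.table(reads, reads_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cell_map <- data.frame(cell_barcode = c("CELL1", "CELL2"),
                         subject_id = "S001", cell_type = "microglia")
  # CELL1: AAAT collapses into AAAA (C); CCCC conflicts (C vs T) and is
  # removed; GGGG is not transcript-assigned. CELL2: TTTA collapses into
  # TTTT but carries G -> cluster conflict, removed; AAAA (T) survives and
  # is independent of CELL1's AAAA.
  expected <- data.frame(subject_id = "S001", cell_type = "microglia",
                         chrom = "chr1", pos = 10177L,
                         allele = c("C", "T"), count = c(1L, 1L))
  list(cell_map = cell_map, expected_counts = expected,
       files = reads_path)
}
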