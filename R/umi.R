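#' Call one consensus allele per UMI within a cell and locus
#'
#' Reads not assigned to a transcript are dropped. For each UMI barcode,
#' the surviving reads must agree on the observed allele: agreeing reads
#' yield one call, while a UMI whose reads carry different alleles is
#' removed entirely (a disagreement indicates a sequencing error in one of
#' the reads).
#'
#' @param reads data frame of read-level records for one cell x locus:
#'   columns `umi`, `allele`, `n_reads`, `transcript_assigned`.
#' @return Data frame of calls: `umi`, `allele`, `n_reads` (supporting
#'   reads).
#' @export
call_umi_alleles <- function(reads) {
  reads <- reads[reads$transcript_assigned, , drop = FALSE]
  if (nrow(reads) == 0L)
    return(data.frame(umi = character(0), allele = character(0),
                      n_reads = integer(0)))
  agg <- stats::aggregate(n_reads ~ umi + allele, data = reads, FUN = sum)
  n_alleles <- table(agg$umi)
  keep <- names(n_alleles)[n_alleles == 1L]
  agg <- agg[agg$umi %in% keep, c("umi", "allele", "n_reads"), drop = FALSE]
  rownames(agg) <- NULL
  agg[order(agg$umi), , drop = FALSE]
}

hamming1 <- function(a, b) {
  # TRUE when the equal-length strings differ at <= 1 position
  if (a == b) return(TRUE)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv) <= 1L
}

#' Collapse UMIs within one mismatch
#'
#' Directional single-mismatch collapsing of UMI allele calls: calls are
#' visited in decreasing order of supporting reads (ties broken
#' lexicographically by UMI), and each call is absorbed into the first
#' already-placed cluster whose seed UMI is within Hamming distance 1;
#' otherwise it seeds a new cluster. A cluster whose members carry
#' different alleles is removed -- the same sequencing-error rationale as
#' the per-UMI conflict rule, applied at the collapsed level.
#'
#' @param calls output of [call_umi_alleles()] (one cell x locus).
#' @return Data frame of surviving collapsed calls: `umi` (cluster seed),
#'   `allele`, `n_reads` (summed over members).
#' @export
collapse_umis <- function(calls) {
  if (nrow(calls) == 0L) return(calls[, c("umi", "allele", "n_reads")])
  if (length(unique(nchar(calls$umi))) != 1L)
    stop("UMIs of unequal length cannot be collapsed")
  ord <- order(-calls$n_reads, calls$umi)
  calls <- calls[ord, , drop = FALSE]
  seed <- character(0)
  assignment <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- 0L
    for (s in seq_along(seed)) {
      if (hamming1(calls$umi[i], seed[s])) { hit <- s; break }
    }
    if (hit == 0L) {
      seed <- c(seed, calls$umi[i])
      hit <- length(seed)
    }
    assignment[i] <- hit
  }
  out <- lapply(seq_along(seed), function(s) {
    members <- calls[assignment == s, , drop = FALSE]
    if (length(unique(members$allele)) > 1L) return(NULL)  # conflict
    data.frame(umi = seed[s], allele = members$allele[1],
               n_reads = sum(members$n_reads))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(umi = character(0), allele = character(0),
                      n_reads = integer(0))
  rownames(out) <- NULL
  out
}

#' Run the per-cell UMI pipeline over a read-level table
#'
#' Applies [call_umi_alleles()] then [collapse_umis()] within every
#' (cell barcode, locus) group of a read-level record table.
#'
#' @param reads data frame with columns `cell_barcode`, `chrom`, `pos`,
#'   `umi`, `allele`, `n_reads`, `transcript_assigned`.
#' @return Data frame of collapsed calls with `cell_barcode`, `chrom`,
#'   `pos`, `umi`, `allele`.
#' @export
umi_allele_calls <- function(reads) {
  groups <- split(reads,
                  list(reads$cell_barcode, reads$chrom, reads$pos),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    calls <- collapse_umis(call_umi_alleles(g))
    if (nrow(calls) == 0L) return(NULL)
    data.frame(cell_barcode = g$cell_barcode[1], chrom = g$chrom[1],
               pos = g$pos[1], umi = calls$umi, allele = calls$allele)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell_barcode = character(0), chrom = character(0),
                      pos = integer(0), umi = character(0),
                      allele = character(0))
  rownames(out) <- NULL
  out
}

#' Aggregate collapsed UMI calls to subject x cell type x locus counts
#'
#' Pseudo-bulk allelic counts: for every subject, cell type and locus, the
#' count of an allele is the number of collapsed UMI calls carrying it,
#' summed over the subject's cells of that type. UMIs are per cell, so the
#' same UMI string in two different cells counts twice. Barcodes absent
#' from the map are dropped (a message reports how many).
#'
#' @param calls output of [umi_allele_calls()].
#' @param cell_map data frame `cell_barcode`, `subject_id`, `cell_type`;
#'   a barcode mapped to two subjects is an error.
#' @return Data frame `subject_id`, `cell_type`, `chrom`, `pos`, `allele`,
#'   `count` (the allelic-count layout of the bulk pipeline plus
#'   `cell_type`).
#' @export
aggregate_to_subject <- function(calls, cell_map) {
  if (anyDuplicated(cell_map$cell_barcode))
    stop("duplicate cell barcode(s) in cell map")
  idx <- match(calls$cell_barcode, cell_map$cell_barcode)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " call(s) from unmapped barcodes dropped")
    calls <- calls[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(calls) == 0L)
    return(data.frame(subject_id = character(0), cell_type = character(0),
                      chrom = character(0), pos = integer(0),
                      allele = character(0), count = integer(0)))
  calls$subject_id <- cell_map$subject_id[idx]
  calls$cell_type <- cell_map$cell_type[idx]
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(calls))),
    by = calls[, c("subject_id", "cell_type", "chrom", "pos", "allele")],
    FUN = sum)
  agg[order(agg$subject_id, agg$cell_type, agg$chrom, agg$pos,
            agg$allele), , drop = FALSE]
}
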