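#' Aggregate per-read haplotype votes into an allelic count table
#'
#' Each RNA-seq read covering at least one heterozygous coding SNP votes for
#' the haplotype whose allele it carries at each covered SNP; the read is
#' assigned to the majority haplotype, and reads with tied votes are
#' discarded (but counted). Genes without a heterozygous coding SNP are not
#' "biallelic" and are excluded from testing.
#'
#' @param votes long data frame with one row per (read, SNP): columns
#'   `read_id`, `gene`, `stage`, `hap` ("A" or "B"), and optionally
#'   `replicate`
#' @return data frame of class `allelic_counts`: per gene x stage
#'   (x replicate), `count_A`, `count_B`, `ties` (discarded reads),
#'   `n_het_snps` (distinct SNP votes observed for the gene)
#' @export
count_alleles <- function(votes) {
  stopifnot(all(c("read_id", "gene", "stage", "hap") %in% names(votes)))
  if (!"replicate" %in% names(votes)) votes$replicate <- 1L
  # majority vote per read
  key <- paste(votes$read_id, votes$gene, votes$stage, votes$replicate, sep = "\r")
  nA <- tapply(votes$hap == "A", key, sum)
  nB <- tapply(votes$hap == "B", key, sum)
  parts <- strsplit(names(nA), "\r", fixed = TRUE)
  rd <- data.frame(gene = vapply(parts, `[`, character(1), 2),
                   stage = vapply(parts, `[`, character(1), 3),
                   replicate = vapply(parts, `[`, character(1), 4),
                   assigned = ifelse(nA > nB, "A", ifelse(nB > nA, "B", "tie")),
                   stringsAsFactors = FALSE)
  gkey <- paste(rd$gene, rd$stage, rd$replicate, sep = "\r")
  cA <- tapply(rd$assigned == "A", gkey, sum)
  cB <- tapply(rd$assigned == "B", gkey, sum)
  ct <- tapply(rd$assigned == "tie", gkey, sum)
  parts <- strsplit(names(cA), "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[`, character(1), 1),
                    stage = vapply(parts, `[`, character(1), 2),
                    replicate = vapply(parts, `[`, character(1), 3),
                    count_A = as.integer(cA), count_B = as.integer(cB),
                    ties = as.integer(ct), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("allelic_counts", "data.frame")
  out
}

#' Test allele-specific expression per gene and stage
#'
#' Two-sided exact binomial test of the haplotype A read count against an
#' expected 0.5 allelic balance, with Benjamini-Hochberg FDR across genes
#' (within each stage by default, matching a per-stage discovery design).
#' Replicates are pooled before testing by default.
#'
#' @param counts an `allelic_counts` table (or compatible data frame with
#'   `gene`, `stage`, `count_A`, `count_B`)
#' @param alpha_ase FDR threshold for the ASE flag
#' @param pool_replicates sum counts over replicates before testing
#' @param fdr_global correct across all stages jointly instead of within
#'   stage
#' @return data frame of class `ase_results`: p-value, FDR, fold change
#'   (high/low allele, `Inf` when the low allele has zero reads),
#'   `high_haplotype`, `ase` flag
#' @export
test_ase <- function(counts, alpha_ase = 0.05, pool_replicates = TRUE,
                     fdr_global = FALSE) {
  x <- as.data.frame(counts)
  if (pool_replicates && "replicate" %in% names(x)) {
    k <- paste(x$gene, x$stage, sep = "\r")
    cA <- tapply(x$count_A, k, sum); cB <- tapply(x$count_B, k, sum)
    parts <- strsplit(names(cA), "\r", fixed = TRUE)
    x <- data.frame(gene = vapply(parts, `[`, character(1), 1),
                    stage = vapply(parts, `[`, character(1), 2),
                    count_A = as.integer(cA), count_B = as.integer(cB),
                    stringsAsFactors = FALSE)
  }
  x <- x[x$count_A + x$count_B >= 1, , drop = FALSE]
  x$p_value <- vapply(seq_len(nrow(x)), function(i)
    binom.test(x$count_A[i], x$count_A[i] + x$count_B[i], 0.5)$p.value,
    numeric(1))
  if (fdr_global) {
    x$fdr <- p.adjust(x$p_value, "BH")
  } else {
    x$fdr <- NA_real_
    for (st in unique(x$stage)) {
      sel <- x$stage == st
      x$fdr[sel] <- p.adjust(x$p_value[sel], "BH")
    }
  }
  hi <- pmax(x$count_A, x$count_B); lo <- pmin(x$count_A, x$count_B)
  x$fold_change <- ifelse(lo == 0, Inf, hi / lo)
  x$high_haplotype <- ifelse(x$count_A >= x$count_B, "A", "B")
  x$high_count <- hi
  x$ase <- x$fdr < alpha_ase
  rownames(x) <- NULL
  class(x) <- c("ase_results", "data.frame")
  x
}

#' Flag extreme allele-specific expression (EASE)
#'
#' EASE requires, simultaneously: fold change strictly above
#' `fold_threshold`, a high-allele read count strictly above
#' `min_high_count`, and FDR below `alpha_ease`. With the default
#' thresholds a gene at fold change exactly 2 or high count exactly 100 is
#' not EASE. EASE implies ASE whenever `alpha_ease <= alpha_ase`.
#'
#' @param results an `ase_results` table from [test_ase()]
#' @param fold_threshold fold-change threshold (strict)
#' @param min_high_count high-allele read count threshold (strict)
#' @param alpha_ease FDR threshold
#' @export
classify_ease <- function(results, fold_threshold = 2, min_high_count = 100,
                          alpha_ease = 0.001) {
  results$ease <- results$fold_change > fold_threshold &
    results$high_count > min_high_count &
    results$fdr < alpha_ease
  results
}

#' Associate EASE genes with heterozygous SVs near their promoters
#'
#' A gene is flagged when any heterozygous SV interval overlaps its putative
#' promoter, the `promoter` bp immediately upstream of the transcription
#' start site on the coding strand (optionally also the gene body). Genes
#' without strand information are skipped with a warning.
#'
#' @param genes data frame with `gene_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open; e.g. `annotation$genes`)
#' @param svs data frame of heterozygous SV intervals: `contig`, `start`,
#'   `end`
#' @param promoter upstream window size, bp
#' @param include_gene_body also flag SVs overlapping the gene body
#' @return list with `genes` (per-gene `promoter_sv` flag) and `fraction`
#'   (flagged / total)
#' @export
promoter_sv_association <- function(genes, svs, promoter = 3000,
                                    include_gene_body = FALSE) {
  no_strand <- is.na(genes$strand) | !genes$strand %in% c("+", "-")
  if (any(no_strand)) {
    warning("skipping ", sum(no_strand), " gene(s) without strand")
    genes <- genes[!no_strand, , drop = FALSE]
  }
  gr_prom <- GenomicRanges::promoters(
    GenomicRanges::GRanges(genes$contig,
                           IRanges::IRanges(genes$start + 1L, genes$end),
                           strand = genes$strand),
    upstream = promoter, downstream = 0)
  gr_sv <- GenomicRanges::GRanges(svs$contig,
                                  IRanges::IRanges(svs$start + 1L, svs$end))
  hit <- IRanges::overlapsAny(gr_prom, gr_sv)
  if (include_gene_body) {
    gr_body <- GenomicRanges::GRanges(genes$contig,
                                      IRanges::IRanges(genes$start + 1L, genes$end))
    hit <- hit | IRanges::overlapsAny(gr_body, gr_sv)
  }
  genes$promoter_sv <- hit
  list(genes = genes, fraction = if (nrow(genes)) mean(hit) else NA_real_)
}
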