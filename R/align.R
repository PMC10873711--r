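#' Build a canonical k-mer index over a set of sequences
#'
#' K-mers are strand-collapsed (a k-mer and its reverse complement share one
#' entry). Contigs shorter than `k` are skipped with a warning.
#'
#' @param seqs named character vector of sequences
#' @param k odd k-mer size, 5 <= k <= 63 (seeding uses 21 by default)
#' @return object of class `kmer_index`
#' @export
build_index <- function(seqs, k = 21) {
  if (k %% 2 != 1 || k < 5 || k > 63) stop("k must be odd and in [5, 63]")
  short <- nchar(seqs) < k
  if (any(short)) {
    warning("skipping contig(s) shorter than k: ",
            paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  xp <- cpp_build_index(names(seqs), unname(seqs), as.integer(k))
  structure(list(ptr = xp, k = k, contigs = names(seqs),
                 lengths = nchar(seqs)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("kmer_index: k =", info$k, "|", info$n_contigs, "contig(s) |",
      format(info$n_positions, big.mark = ","), "positions |",
      format(info$n_distinct, big.mark = ","), "distinct k-mers (",
      format(info$n_unique, big.mark = ","), "unique)\n")
  invisible(x)
}

#' Index summary statistics
#' @param index a `kmer_index`
#' @export
index_stats <- function(index) cpp_index_info(index$ptr)

#' Look up k-mers in an index
#' @param index a `kmer_index`
#' @param kmers character vector of k-mers (length k each)
#' @return list of data frames with `contig` (name), `pos` (0-based),
#'   `strand` (0 = query matches indexed orientation, 1 = reverse complement)
#' @export
index_lookup <- function(index, kmers) {
  res <- cpp_index_lookup(index$ptr, kmers)
  lapply(res, function(df) {
    df$contig <- index$contigs[df$contig]
    df
  })
}

#' Map paired-end reads against a single- or dual-haplotype reference
#'
#' A minimal exact-k-mer-seeded mapper: seeds vote for candidate diagonals,
#' candidates are verified by banded unit-cost alignment, and the placement
#' with the minimum edit distance wins. Exact ties are retained in `alts`
#' with MAPQ 0 and broken lexicographically by (contig, position); an
#' ambiguous mate whose partner maps uniquely is rescued through proper-pair
#' consistency (MAPQ 20). MAPQ is otherwise 60 for a unique best placement
#' at least 2 edits better than the runner-up, 30 for a 1-edit margin.
#'
#' @param reads data frame from [simulate_reads()] (columns `id`, `seq1`,
#'   `seq2`), or a character vector of single-end sequences
#' @param reference named character vector: haplotype A only (single mode)
#'   or both haplotypes (dual mode); alternatively a `diploid_genome` with
#'   `mode` selecting the reference
#' @param mode "dual" or "single" (used when `reference` is a genome)
#' @param k seed k-mer size
#' @param band alignment band half-width (also the maximum detectable InDel)
#' @param max_nm maximum edit distance for a valid placement
#' @param insert insert-size mean and sd for proper-pair rescue
#' @param max_occ seeds occurring more often than this are skipped
#' @param sam_out optional SAM output path
#' @return alignment data frame (one row per mate) with 0-based `pos`
#' @export
map_reads <- function(reads, reference, mode = c("dual", "single"), k = 21,
                      band = 32, max_nm = 15, insert = c(400, 60),
                      max_occ = 64, sam_out = NULL) {
  mode <- match.arg(mode)
  if (inherits(reference, "diploid_genome")) {
    reference <- if (mode == "dual") c(reference$hapA, reference$hapB)
                 else reference$hapA
  }
  idx <- if (inherits(reference, "kmer_index")) reference
         else build_index(reference, k)
  single_end <- is.character(reads)
  if (single_end) {
    reads <- data.frame(id = paste0("r", seq_along(reads)), seq1 = reads,
                        stringsAsFactors = FALSE)
  }
  paired <- "seq2" %in% names(reads)
  res <- cpp_map_pairs(idx$ptr, reads$seq1,
                       if (paired) reads$seq2 else character(0),
                       as.integer(band), as.integer(max_nm),
                       insert[1], insert[2], 4L, as.integer(max_occ))
  res$contig <- ifelse(is.na(res$contig), NA_character_, idx$contigs[res$contig])
  res$id <- reads$id[res$read]
  res$seq <- ifelse(res$mate == 1, reads$seq1[res$read],
                    if (paired) reads$seq2[res$read] else NA_character_)
  attr(res, "ref_names") <- idx$contigs
  attr(res, "ref_lengths") <- unname(idx$lengths)
  attr(res, "mode") <- mode
  if (!is.null(sam_out)) write_sam(res, sam_out)
  res
}

#' Pile up alignments into per-position allele counts
#'
#' @param aln alignment data frame from [map_reads()] or [read_sam()]
#' @param reference named character vector of reference sequences
#' @param min_mapq reads below this MAPQ are excluded from allele counts but
#'   tallied into the low-MAPQ depth track. The default 0 counts everything:
#'   exact ties are placed deterministically (lexicographic) and the dual-mode
#'   genotyper's mixed state models the resulting cross-mapping, which is what
#'   lets mutations in regions identical between the haplotypes be recovered
#'   and deduplicated rather than dropped
#' @return object of class `pileup`: per-contig 4 x L base-count matrices
#'   (rows A,C,G,T), low-MAPQ depth vectors, and InDel allele tables
#'   (`ins`, `del`, anchored at the base before the event)
#' @export
pileup <- function(aln, reference, min_mapq = 0) {
  contig_i <- match(aln$contig, names(reference))
  ok <- !is.na(contig_i)
  pl <- cpp_pileup(names(reference), unname(reference),
                   contig_i[ok], aln$pos[ok], aln$strand[ok], aln$cigar[ok],
                   aln$mapq[ok], aln$seq[ok], as.integer(min_mapq))
  names(pl$counts) <- names(reference)
  names(pl$lowq) <- names(reference)
  for (m in seq_along(pl$counts)) rownames(pl$counts[[m]]) <- BASES
  pl$ins$contig <- names(reference)[pl$ins$contig]
  pl$del$contig <- names(reference)[pl$del$contig]
  pl$reference <- reference
  pl$min_mapq <- min_mapq
  class(pl) <- "pileup"
  pl
}

#' Extract pileup columns for a region
#'
#' Returns one row per position with nonzero depth: depth, per-base counts
#' and the fraction of low-MAPQ (excluded) reads.
#'
#' @param pl a [pileup()]
#' @param contig contig name
#' @param from,to 0-based half-open range (defaults to the whole contig)
#' @export
pileup_columns <- function(pl, contig, from = 0, to = NULL) {
  cm <- pl$counts[[contig]]
  if (is.null(to)) to <- ncol(cm)
  idx <- (from + 1):to
  depth <- colSums(cm[, idx, drop = FALSE])
  lowq <- pl$lowq[[contig]][idx]
  keep <- depth > 0 | lowq > 0
  data.frame(contig = contig, pos = idx[keep] - 1L, depth = depth[keep],
             A = cm[1, idx[keep]], C = cm[2, idx[keep]],
             G = cm[3, idx[keep]], T = cm[4, idx[keep]],
             mapq0_frac = lowq[keep] / pmax(1, depth[keep] + lowq[keep]),
             stringsAsFactors = FALSE)
}

#' Paint windows of a genome by donor ancestry using donor-specific k-mers
#'
#' Donor-specific k-mer sets are `kmers(P) \ kmers(M)` and `kmers(M) \
#' kmers(P)`; each window of the target is scored by the fraction of its
#' k-mers found in either set (fractions sum to 1 with the unassigned rest).
#'
#' @param target named character vector (e.g. one haplotype)
#' @param donorP,donorM named character vectors of donor genomes
#' @param k k-mer size
#' @param window window size in bp (must be >= k)
#' @return data frame with per-window donor fractions and the majority call
#' @export
paint_ancestry <- function(target, donorP, donorM, k = 21, window = 50000) {
  if (window < k) stop("window must be >= k")
  sp <- cpp_kmerset_build(unname(donorP), as.integer(k))
  sm <- cpp_kmerset_build(unname(donorM), as.integer(k))
  ponly <- cpp_kmerset_diff(sp, sm)
  monly <- cpp_kmerset_diff(sm, sp)
  out <- list()
  for (ctg in names(target)) {
    w <- cpp_paint_windows(target[[ctg]], as.integer(k), as.integer(window),
                           ponly, monly)
    w$contig <- ctg
    out[[ctg]] <- w
  }
  res <- do.call(rbind, out)
  res$majority <- ifelse(is.na(res$frac_p), NA_character_,
                         ifelse(res$frac_p >= res$frac_m, "P", "M"))
  rownames(res) <- NULL
  res[, c("contig", "start", "end", "frac_p", "frac_m", "frac_unassigned",
          "n_kmers", "majority")]
}

#' Unique k-mer divergence between two sequence sets
#'
#' For each contig of `x`, among k-mers occurring exactly once in that
#' contig, the fraction absent from `y` anywhere. Ratio is monotone
#' non-decreasing in k for fixed sequences.
#'
#' @param x named character vector (query)
#' @param y character vector (subject)
#' @param k k-mer size (21 and 61 are the conventional choices)
#' @return data frame with per-contig ratios and a genome-wide summary row
#' @export
kmer_divergence <- function(x, y, k = 21) {
  res <- cpp_kmer_divergence(names(x), unname(x), unname(y), as.integer(k))
  tot <- sum(res$n_unique)
  rbind(res, data.frame(contig = "genome", n_unique = tot,
                        n_absent = sum(res$n_absent),
                        ratio = if (tot > 0) sum(res$n_absent) / tot else NA))
}
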