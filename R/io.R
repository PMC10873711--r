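#' Write sequences to FASTA
#' @param seqs named character vector
#' @param file output path
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, file, width = 60) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file, width = width)
  invisible(file)
}

#' Read a FASTA file into a named character vector
#' @param file path
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write paired reads to a pair of FASTQ files (Phred+33, constant Q30)
#' @param reads data frame with `id`, `seq1`, `seq2`
#' @param prefix output prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`
#' @export
write_fastq <- function(reads, prefix) {
  for (mate in 1:2) {
    s <- reads[[paste0("seq", mate)]]
    qual <- vapply(nchar(s), function(n) strrep("?", n), character(1))
    lines <- as.vector(rbind(paste0("@", reads$id, "/", mate), s, "+", qual))
    writeLines(lines, paste0(prefix, "_", mate, ".fastq"))
  }
  invisible(prefix)
}

#' Read a FASTQ file
#' @param file path
#' @return data frame with `id`, `seq`
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Minimal SAM 1.6 output: `@HD`/`@SQ` header, FLAG (paired/strand/mate),
#' 1-based POS, CIGAR, and an `NM` tag. Sequences are stored in reference
#' orientation as SAM requires.
#'
#' @param aln alignment data frame from [map_reads()]
#' @param file output path
#' @export
write_sam <- function(aln, file) {
  ref_names <- attr(aln, "ref_names")
  ref_lengths <- attr(aln, "ref_lengths")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", ref_names, "\tLN:", ref_lengths))
  paired <- "mate" %in% names(aln) && any(aln$mate == 2)
  mapped <- !is.na(aln$contig)
  flag <- integer(nrow(aln))
  if (paired) {
    flag <- flag + 1L
    flag <- flag + ifelse(aln$mate == 1, 64L, 128L)
  }
  flag <- flag + ifelse(mapped & aln$strand == 1, 16L, 0L)
  flag <- flag + ifelse(mapped, 0L, 4L)
  seq_out <- ifelse(mapped & aln$strand == 1, revcomp(aln$seq), aln$seq)
  rec <- paste(aln$id, flag,
               ifelse(mapped, aln$contig, "*"),
               ifelse(mapped, aln$pos + 1L, 0L),
               ifelse(mapped, aln$mapq, 0L),
               ifelse(mapped, aln$cigar, "*"),
               "*", 0L, 0L, seq_out,
               vapply(nchar(aln$seq), function(n) strrep("?", n), character(1)),
               ifelse(mapped, paste0("NM:i:", aln$nm), ""),
               sep = "\t")
  rec <- sub("\t$", "", rec)
  writeLines(c(hdr, rec), file)
  invisible(file)
}

#' Read a SAM file into an alignment data frame
#' @param file path
#' @export
read_sam <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_names <- sub(".*SN:([^\t]+).*", "\\1", sq)
  ref_lengths <- as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  rec <- lines[!startsWith(lines, "@")]
  if (!length(rec)) {
    out <- data.frame(id = character(), contig = character(), pos = integer(),
                      strand = integer(), mapq = integer(), cigar = character(),
                      seq = character(), nm = integer(), mate = integer(),
                      stringsAsFactors = FALSE)
  } else {
    f <- strsplit(rec, "\t")
    flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
    mapped <- bitwAnd(flag, 4L) == 0L
    strand <- ifelse(bitwAnd(flag, 16L) > 0L, 1L, 0L)
    nm <- vapply(f, function(x) {
      tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
      if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
    }, integer(1))
    seqs <- vapply(f, `[`, character(1), 10)
    out <- data.frame(
      id = vapply(f, `[`, character(1), 1),
      contig = ifelse(mapped, vapply(f, `[`, character(1), 3), NA_character_),
      pos = ifelse(mapped, vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L, NA_integer_),
      strand = ifelse(mapped, strand, NA_integer_),
      mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
      cigar = ifelse(mapped, vapply(f, `[`, character(1), 6), NA_character_),
      seq = ifelse(mapped & strand == 1L, vapply(seqs, cpp_revcomp, character(1), USE.NAMES = FALSE), seqs),
      nm = nm,
      mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
      stringsAsFactors = FALSE)
  }
  attr(out, "ref_names") <- ref_names
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Write somatic calls as VCF 4.2
#'
#' INFO keys: `MODE` (single/dual), `HAP` (A or B), `HOMPOS` (homologous
#' coordinate on the partner haplotype), `DUPGRP` (duplicate group id),
#' `SHARED` (flag: allele observed at ~50% on one haplotype contig, i.e. the
#' two copies could not be separated), `GT` (diploid genotype, single mode).
#'
#' @param calls somatic call data frame
#' @param file output path
#' @param ref_names,ref_lengths contig metadata for the header
#' @export
write_vcf <- function(calls, file, ref_names = NULL, ref_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapsoma",
           if (!is.null(ref_names))
             paste0("##contig=<ID=", ref_names, ",length=", ref_lengths, ">"),
           "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Calling mode\">",
           "##INFO=<ID=HAP,Number=1,Type=String,Description=\"Haplotype carrying the allele\">",
           "##INFO=<ID=HOMPOS,Number=1,Type=String,Description=\"Homologous position on partner haplotype\">",
           "##INFO=<ID=DUPGRP,Number=1,Type=Integer,Description=\"Homologous duplicate group\">",
           "##INFO=<ID=SHARED,Number=0,Type=Flag,Description=\"Ambiguous between haplotype copies\">",
           "##INFO=<ID=GT,Number=1,Type=String,Description=\"Called genotype\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt allele depth\">",
           "##FILTER=<ID=LOWQUAL,Description=\"Quality below threshold\">",
           "##FILTER=<ID=LOWDEPTH,Description=\"Depth below threshold\">",
           "##FILTER=<ID=BLACKLIST,Description=\"Null-simulation artifact position\">",
           "##FILTER=<ID=DUP,Description=\"Duplicate of a homologous call\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!nrow(calls)) {
    writeLines(hdr, file)
    return(invisible(file))
  }
  info <- paste0("MODE=", calls$mode,
                 ifelse(!is.na(calls$haplotype), paste0(";HAP=", calls$haplotype), ""),
                 ifelse(!is.na(calls$hom_pos), paste0(";HOMPOS=", calls$hom_pos), ""),
                 ifelse(!is.na(calls$dup_group), paste0(";DUPGRP=", calls$dup_group), ""),
                 ifelse(isTRUE_vec(calls$shared), ";SHARED", ""),
                 ifelse(!is.na(calls$genotype), paste0(";GT=", calls$genotype), ""),
                 paste0(";DP=", calls$depth, ";AD=", calls$alt_count))
  rec <- paste(calls$contig, calls$pos + 1L, ".", calls$ref, calls$alt,
               formatC(calls$qual, format = "f", digits = 1),
               calls$filter, info, sep = "\t")
  writeLines(c(hdr, rec), file)
  invisible(file)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read a hapsoma VCF back into a somatic call data frame
#' @param file path
#' @export
read_vcf <- function(file) {
  lines <- readLines(file)
  rec <- lines[!startsWith(lines, "#")]
  cols <- c("contig", "pos", "ref", "alt", "qual", "filter", "mode",
            "haplotype", "hom_pos", "dup_group", "shared", "genotype",
            "depth", "alt_count")
  if (!length(rec)) {
    out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  f <- strsplit(rec, "\t")
  getinfo <- function(info, key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    out <- rep(NA_character_, length(info))
    hit <- m > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
    out
  }
  info <- vapply(f, `[`, character(1), 8)
  data.frame(
    contig = vapply(f, `[`, character(1), 1),
    pos = as.integer(vapply(f, `[`, character(1), 2)) - 1L,
    ref = vapply(f, `[`, character(1), 4),
    alt = vapply(f, `[`, character(1), 5),
    qual = as.numeric(vapply(f, `[`, character(1), 6)),
    filter = vapply(f, `[`, character(1), 7),
    mode = getinfo(info, "MODE"),
    haplotype = getinfo(info, "HAP"),
    hom_pos = getinfo(info, "HOMPOS"),
    dup_group = suppressWarnings(as.integer(getinfo(info, "DUPGRP"))),
    shared = grepl("(^|;)SHARED(;|$)", info),
    genotype = getinfo(info, "GT"),
    depth = as.integer(sub(".*;DP=([0-9]+).*", "\\1", info)),
    alt_count = as.integer(sub(".*;AD=([0-9]+).*", "\\1", info)),
    stringsAsFactors = FALSE)
}

#' Write a pairwise distance matrix as a NEXUS DISTANCES block
#' @param d symmetric matrix with dimnames
#' @param file path
#' @export
write_nexus_distances <- function(d, file) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  n <- nrow(d)
  lines <- c("#NEXUS", "", "BEGIN TAXA;",
             paste0("  DIMENSIONS NTAX=", n, ";"),
             paste0("  TAXLABELS ", paste(rownames(d), collapse = " "), ";"),
             "END;", "", "BEGIN DISTANCES;",
             "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
             "  MATRIX")
  for (i in seq_len(n)) {
    lines <- c(lines, paste0("    ", rownames(d)[i], " ",
                             paste(formatC(d[i, ], format = "g", digits = 10),
                                   collapse = " ")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, file)
  invisible(file)
}

#' Parse a NEXUS DISTANCES block written by [write_nexus_distances()]
#' @param file path
#' @export
read_nexus_distances <- function(file) {
  lines <- readLines(file)
  i0 <- grep("MATRIX", lines)[1]
  i1 <- grep("^\\s*;", lines)
  i1 <- i1[i1 > i0][1]
  rows <- trimws(lines[(i0 + 1):(i1 - 1)])
  parts <- strsplit(rows, "\\s+")
  labs <- vapply(parts, `[`, character(1), 1)
  d <- t(vapply(parts, function(x) as.numeric(x[-1]), numeric(length(parts))))
  dimnames(d) <- list(labs, labs)
  d
}

#' Write a BED file (0-based half-open)
#' @param df data frame with contig, start, end and optional extra columns
#' @param file path
#' @export
write_bed <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
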