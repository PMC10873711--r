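# shared small fixtures, built once per test run
.fx <- new.env()

# 100-kb sweet-orange-like genome with full structural repertoire
fx_genome <- function() {
  if (is.null(.fx$g)) {
    .fx$g <- generate_diploid(genome_config(c(chr1 = 100000), seed = 7))
  }
  .fx$g
}

# SNP-only genome (no InDels, no segments): hapA and hapB are colinear
fx_snp_genome <- function() {
  if (is.null(.fx$gsnp)) {
    .fx$gsnp <- generate_diploid(genome_config(
      c(chr1 = 50000), snp_rate = 0.018, indel_rate = 0,
      hap_specific_per_mb = 0, seed = 3))
  }
  .fx$gsnp
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# independent semi-global edit distance oracle (pattern-global/subject-local)
oracle_edit_distance <- function(read, ref) {
  al <- Biostrings::pairwiseAlignment(
    pattern = read, subject = ref, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 0, mismatch = -1, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 1)
  -Biostrings::score(al)
}

# toy annotation on a small genome; returns list(ann, genome seqs)
fx_annotation <- function(n_genes = 30, len = 120000, seed = 5) {
  seqs <- c(chrT = random_seq(len, seed = seed))
  synthesize_annotation(seqs, n_genes = n_genes, cds_len = c(300, 900),
                        promoter_gap = 1200, seed = seed)
}

# brute-force effect of a coding SNP by translating the whole mutated CDS
oracle_effect <- function(ann, contig, pos, alt) {
  hit <- ann$cds[ann$cds$contig == contig & pos >= ann$cds$start &
                   pos < ann$cds$end, , drop = FALSE]
  if (!nrow(hit)) return("noncoding")
  g <- hit$gene_id[1]
  gene <- ann$genes[ann$genes$gene_id == g, ]
  s <- ann$seqs[[contig]]
  mut <- paste0(substring(s, 1, pos), alt, substring(s, pos + 2))
  cds_old <- substring(s, gene$start + 1, gene$end)
  cds_new <- substring(mut, gene$start + 1, gene$end)
  if (gene$strand == "-") {
    cds_old <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_old)))
    cds_new <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_new)))
  }
  p_old <- as.character(Biostrings::translate(Biostrings::DNAString(cds_old),
                                              no.init.codon = TRUE))
  p_new <- as.character(Biostrings::translate(Biostrings::DNAString(cds_new),
                                              no.init.codon = TRUE))
  if (p_old == p_new) return("synonymous")
  d <- which(strsplit(p_old, "")[[1]] != strsplit(p_new, "")[[1]])[1]
  aa_old <- substring(p_old, d, d); aa_new <- substring(p_new, d, d)
  if (aa_new == "*") "stop_gain"
  else if (aa_old == "*") "stop_loss"
  else if (d == 1 && aa_old == "M") "start_loss"
  else "missense"
}
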