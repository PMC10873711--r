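test_that("zero-rate config yields identical haplotypes and an identity map", {
  g <- generate_diploid(genome_config(c(chr1 = 20000), snp_rate = 0,
                                      indel_rate = 0, hap_specific_per_mb = 0,
                                      seed = 1))
  expect_identical(unname(g$hapA), unname(g$hapB))
  expect_equal(nrow(g$homology$blocks), 1)
  expect_equal(g$homology$blocks$a1 - g$homology$blocks$a0, 20000)
  p <- c(0L, 123L, 19999L)
  expect_identical(homology_lookup(g$homology, "chr1", p, "A"), p)
})

test_that("config validation rejects saturated rates and short contigs", {
  expect_error(genome_config(c(chr1 = 20000), snp_rate = 0.75), "0.75")
  expect_error(genome_config(c(chr1 = 5000)), "10 kb")
})

test_that("germline SNP count is consistent with the binomial target density", {
  g <- fx_snp_genome()
  # recount heterozygous sites by direct comparison through the truth map
  a <- strsplit(g$hapA[[1]], "")[[1]]
  b <- strsplit(g$hapB[[1]], "")[[1]]
  pos <- 0:(length(a) - 1)
  pb <- homology_lookup(g$homology, "chr1", pos, "A")
  n_diff <- sum(a[pos + 1] != b[pb + 1], na.rm = TRUE)
  n <- 50000; p <- 0.018
  expect_lt(abs(n_diff - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  expect_equal(n_diff, sum(g$germline$kind == "SNP"))
})

test_that("reapplying the germline variant list reconstructs haplotype B", {
  g <- generate_diploid(genome_config(c(chr1 = 30000), snp_rate = 0.01,
                                      indel_rate = 0.002,
                                      hap_specific_per_mb = 0, seed = 9))
  germ <- g$germline
  germ <- germ[order(-germ$posA), , drop = FALSE] # right-to-left
  s <- g$hapA[["chr1_A"]]
  for (i in seq_len(nrow(germ))) {
    p <- germ$posA[i]
    expect_identical(substring(s, p + 1, p + nchar(germ$refA[i])), germ$refA[i])
    s <- paste0(substring(s, 1, p), germ$altB[i],
                substring(s, p + 1 + nchar(germ$refA[i])))
  }
  expect_identical(s, unname(g$hapB[["chr1_B"]]))
})

test_that("identical seed reproduces the genome and the reads byte-for-byte", {
  cfg <- genome_config(c(chr1 = 20000), seed = 42)
  g1 <- generate_diploid(cfg)
  g2 <- generate_diploid(cfg)
  expect_identical(g1$hapB, g2$hapB)
  expect_identical(g1$germline, g2$germline)
  r1 <- simulate_reads(g1, 10)
  r2 <- simulate_reads(g2, 10)
  expect_identical(r1, r2)
})

test_that("spiked somatic mutations are heterozygous, collision-free and
           spread over contigs in proportion to length", {
  g2 <- generate_diploid(genome_config(c(chrA = 100000, chrB = 50000),
                                       snp_rate = 0.005, seed = 2))
  tr <- spike_somatic(g2, 0)
  expect_equal(nrow(tr), 0)
  tr <- spike_somatic(g2, 600, seed = 21)
  expect_equal(nrow(tr), 600)
  # ref matches the carrying haplotype
  seqs <- c(g2$hapA, g2$hapB)
  ok <- vapply(seq_len(nrow(tr)), function(i)
    substring(seqs[[tr$contig[i]]], tr$pos[i] + 1,
              tr$pos[i] + nchar(tr$ref[i])) == tr$ref[i], logical(1))
  expect_true(all(ok))
  # no collisions within a haplotype contig
  expect_false(any(duplicated(tr[, c("contig", "pos")])))
  # counts proportional to length across base contigs
  base <- sub("_[AB]$", "", tr$contig)
  obs <- table(factor(base, c("chrA", "chrB")))
  pv <- chisq.test(obs, p = c(2, 1) / 3)$p.value
  expect_gt(pv, 0.01)
})

test_that("alt bases follow the supplied substitution matrix row", {
  g <- fx_snp_genome()
  m <- jc_matrix()
  m$prob["A", ] <- c(0, 1, 0, 0) # force A->C
  tr <- spike_somatic(g, 300, matrix = m, indel_fraction = 0, seed = 5)
  a_rows <- tr[tr$ref == "A", ]
  expect_gt(nrow(a_rows), 10)
  expect_true(all(a_rows$alt == "C"))
})

test_that("read simulation conserves total bases and hits the error rate", {
  g <- fx_snp_genome()
  expect_equal(nrow(simulate_reads(g, 0)), 0)
  expect_error(simulate_reads(g, 10, insert = c(100, 10)), "insert")
  reads <- simulate_reads(g, 35, seed = 13)
  total <- sum(nchar(reads$seq1)) + sum(nchar(reads$seq2))
  expect_lt(abs(total - 35 * 50000), 0.01 * 35 * 50000)
  # recount substitution errors against the truth origins
  seqs <- c(g$hapA, g$hapB)
  sub <- reads[1:2000, ]
  mm <- 0; nb <- 0
  for (i in seq_len(nrow(sub))) {
    src <- seqs[[sub$contig[i]]]
    for (m in 1:2) {
      p <- sub[[paste0("pos", m)]][i]
      s <- sub[[paste0("seq", m)]][i]
      truth <- substring(src, p + 1, p + nchar(s))
      if (sub[[paste0("strand", m)]][i] == 1) truth <- revcomp(truth)
      mm <- mm + sum(strsplit(s, "")[[1]] != strsplit(truth, "")[[1]])
      nb <- nb + nchar(s)
    }
  }
  expect_lt(abs(mm / nb - 0.002), 3 * sqrt(0.002 * 0.998 / nb))
})

test_that("clonal population mutations accumulate along root-to-leaf paths", {
  g <- fx_snp_genome()
  # single-leaf tree behaves like a plain spike
  tree1 <- clone_tree(data.frame(parent = "root", child = "acc1"))
  pop1 <- simulate_clonal_population(g, tree1, 40, reads = FALSE, seed = 31)
  expect_setequal(pop1$leaf_mutations$acc1, pop1$truth$id)

  tree <- balanced_clone_tree(n_ingroup = 7, n_outgroup = 3)
  pop <- simulate_clonal_population(g, tree, 50 * nrow(tree$edges),
                                    reads = FALSE, seed = 32)
  # brute-force path enumeration: shared mutations between two leaves equal
  # the mutations on the shared prefix of their root paths
  leaves <- tree$leaves
  for (i in seq_along(leaves)) for (j in seq_along(leaves)) {
    if (j <= i) next
    shared_branches <- intersect(leaf_path(tree, leaves[i]),
                                 leaf_path(tree, leaves[j]))
    expected <- pop$truth$id[pop$truth$branch %in% shared_branches]
    got <- intersect(pop$leaf_mutations[[leaves[i]]],
                     pop$leaf_mutations[[leaves[j]]])
    expect_setequal(got, expected)
  }
  # outgroup leaves carry only outgroup-branch mutations
  og_branches <- unique(unlist(lapply(tree$outgroup, leaf_path, tree = tree)))
  for (o in tree$outgroup) {
    expect_true(all(pop$truth$branch[pop$truth$id %in% pop$leaf_mutations[[o]]]
                    %in% og_branches))
  }
})

test_that("FASTA/FASTQ output round-trips through the package readers", {
  g <- fx_snp_genome()
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(g$hapA, g$hapB), fa)
  back <- read_fasta(fa)
  expect_identical(back, c(g$hapA, g$hapB))
  reads <- simulate_reads(g, 2, seed = 4)
  pre <- tempfile()
  write_fastq(reads, pre)
  r1 <- read_fastq(paste0(pre, "_1.fastq"))
  expect_identical(r1$seq, reads$seq1)
  expect_identical(r1$id, paste0(reads$id, "/1"))
})
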