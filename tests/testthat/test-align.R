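test_that("index counts k-mers and flags validity of k", {
  idx <- build_index(c(x = "ACGTACGT"), k = 5)
  # L - k + 1 positions (subtracting nothing: no ambiguous bases)
  expect_equal(index_stats(idx)$n_positions, 4)
  expect_error(build_index(c(x = "ACGT"), k = 4), "odd")
  expect_warning(build_index(c(x = "ACGTACGTACGTACG", y = "ACG"), k = 11),
                 "shorter")
})

test_that("every indexed position re-extracts its own k-mer", {
  s <- random_seq(10000, seed = 2)
  idx <- build_index(c(ctg = s), k = 21)
  pos <- sort(sample(0:(10000 - 21), 300))
  kmers <- substring(s, pos + 1, pos + 21)
  hits <- index_lookup(idx, kmers)
  for (i in seq_along(pos)) {
    expect_true(pos[i] %in% hits[[i]]$pos)
    expect_true(all(hits[[i]]$strand[hits[[i]]$pos == pos[i]] == 0))
  }
  # reverse complement finds the same position on the opposite strand
  rc_hits <- index_lookup(idx, revcomp(kmers[1]))
  expect_true(pos[1] %in% rc_hits[[1]]$pos)
  expect_equal(rc_hits[[1]]$strand[rc_hits[[1]]$pos == pos[1]], 1)
})

test_that("unique exact reads map with NM 0 and MAPQ 60", {
  s <- random_seq(20000, seed = 6)
  aln <- map_reads(substring(s, 5001, 5150), c(ctg = s))
  expect_equal(aln$pos, 5000)
  expect_equal(aln$nm, 0)
  expect_equal(aln$mapq, 60)
  expect_equal(aln$cigar, "150M")
})

test_that("reads from a region identical between haplotypes tie with MAPQ 0", {
  s <- random_seq(20000, seed = 8)
  ref <- c(chr_A = s, chr_B = s)
  aln <- map_reads(substring(s, 1001, 1150), ref)
  expect_equal(aln$mapq, 0)
  expect_equal(aln$nties, 2)
  # lexicographic tie-break keeps the A contig
  expect_equal(aln$contig, "chr_A")
  expect_match(aln$alts, "chr_B:1000")
})

test_that("unmapped reads yield flagged records, not errors", {
  s <- random_seq(20000, seed = 9)
  foreign <- random_seq(150, seed = 99)
  aln <- map_reads(foreign, c(ctg = s))
  expect_true(is.na(aln$contig))
})

test_that("best placement edit distance matches an exhaustive alignment oracle", {
  skip_if_not_installed("withr")
  s <- random_seq(4000, seed = 10)
  g <- list(ref = c(ctg = s))
  set.seed(11)
  cases <- list()
  for (i in 1:25) {
    p <- sample(0:(4000 - 160), 1)
    rd <- substring(s, p + 1, p + 150)
    v <- strsplit(rd, "")[[1]]
    nerr <- sample(0:3, 1)
    for (t in sample(150, nerr)) v[t] <- sample(c("A", "C", "G", "T"), 1)
    rd <- paste(v, collapse = "")
    if (i %% 3 == 0) { # inject a small deletion
      d <- sample(1:8, 1); q <- sample(30:100, 1)
      rd <- paste0(substring(rd, 1, q), substring(rd, q + d + 1))
    }
    cases[[i]] <- rd
  }
  aln <- map_reads(unlist(cases), g$ref)
  for (i in seq_along(cases)) {
    if (is.na(aln$contig[i])) next
    expect_equal(aln$nm[i], oracle_edit_distance(cases[[i]], s),
                 info = paste("case", i))
  }
})

test_that("pileup counts depths, InDel alleles and conserves aligned bases", {
  s <- random_seq(2000, seed = 12)
  ref <- c(ctg = s)
  rd <- substring(s, 501, 650)
  aln <- map_reads(rep(rd, 10), ref)
  pl <- pileup(aln, ref)
  cols <- pileup_columns(pl, "ctg")
  expect_equal(nrow(cols), 150)
  expect_true(all(cols$depth == 10))
  expect_true(all(apply(cols[, c("A", "C", "G", "T")], 1, max) == 10))
  # conservation: column depths equal aligned M bases
  expect_equal(sum(cols$depth), sum(!is.na(aln$contig)) * 150)
  # a 2-bp deletion registers at its anchor column
  rd_del <- paste0(substring(s, 501, 570), substring(s, 573, 652))
  pl2 <- pileup(map_reads(rep(rd_del, 5), ref), ref)
  expect_true(any(pl2$del$pos == 569 & pl2$del$len == 2 & pl2$del$count == 5))
})

test_that("error-free simulation gives monoallelic non-variant columns", {
  g <- fx_snp_genome()
  reads <- simulate_reads(g, 8, error_rate = 0, seed = 17)
  dual <- c(g$hapA, g$hapB)
  pl <- pileup(map_reads(reads, dual), dual)
  for (ctg in names(dual)) {
    cm <- pl$counts[[ctg]]
    depth <- colSums(cm)
    expect_true(all(apply(cm, 2, max) == depth)) # one allele per column
  }
})

test_that("ancestry painting recovers the donor mosaic", {
  cfg <- genome_config(c(chr1 = 200000), snp_rate = 0.002, indel_rate = 0,
                       hap_specific_per_mb = 0,
                       ancestry = list(donor_divergence = 0.02,
                                       block_mean_len = 25000),
                       seed = 14)
  g <- generate_diploid(cfg)
  expect_error(paint_ancestry(g$hapA, g$donors$P, g$donors$M, k = 21,
                              window = 10), "window")
  paint <- paint_ancestry(g$hapA, g$donors$P, g$donors$M, k = 21,
                          window = 10000)
  expect_true(all(abs(paint$frac_p + paint$frac_m + paint$frac_unassigned - 1)
                  < 1e-9))
  # majority call per window vs the truth blocks
  anc <- g$ancestry[g$ancestry$haplotype_id == "A", ]
  truth_major <- vapply(seq_len(nrow(paint)), function(i) {
    ov <- pmin(anc$end, paint$end[i]) - pmax(anc$start, paint$start[i])
    donors <- tapply(pmax(ov, 0), anc$donor, sum)
    names(which.max(donors))
  }, character(1))
  expect_gte(mean(paint$majority == truth_major), 0.95)
})

test_that("unique-kmer divergence is zero on self and monotone in k", {
  g <- fx_snp_genome()
  self <- kmer_divergence(g$hapA, g$hapA, k = 21)
  expect_equal(self$ratio[self$contig == "genome"], 0)
  d21 <- kmer_divergence(g$hapA, g$hapB, k = 21)
  d61 <- kmer_divergence(g$hapA, g$hapB, k = 61)
  expect_gt(d61$ratio[d61$contig == "genome"],
            d21$ratio[d21$contig == "genome"])
  # unrelated random sequences share essentially nothing
  x <- c(a = random_seq(100000, seed = 1))
  y <- c(b = random_seq(100000, seed = 2))
  expect_gt(kmer_divergence(x, y, 21)$ratio[2], 0.99)
})

test_that("SAM output round-trips through the package reader", {
  g <- fx_snp_genome()
  reads <- simulate_reads(g, 1, seed = 19)[1:50, ]
  dual <- c(g$hapA, g$hapB)
  aln <- map_reads(reads, dual)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, f)
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(aln))
  m <- !is.na(aln$contig)
  expect_equal(back$contig[m], aln$contig[m])
  expect_equal(back$pos[m], aln$pos[m])
  expect_equal(back$cigar[m], aln$cigar[m])
  expect_equal(back$nm[m], aln$nm[m])
  expect_equal(back$seq[m], aln$seq[m]) # reader restores original orientation
})
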