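test_that("dual-mode genotyping calls a fixed alt allele with high confidence", {
  gs <- genotype_site(c(A = 0, C = 30), ref = "A", mode = "dual")
  expect_equal(gs$name, "A:C")
  expect_gt(gs$qual, 50)
  # balanced column: the 50:50 mixed state wins
  gm <- genotype_site(c(A = 15, C = 15), ref = "A", mode = "dual")
  expect_true(gm$mixed)
  expect_gt(gm$qual, 50)
  # low-fraction residue never reaches calling confidence: the noise state
  # absorbs enough posterior to keep the variant quality below threshold
  gn <- genotype_site(c(A = 12, C = 2), ref = "A", mode = "dual")
  expect_lt(gn$qual, 50)
  gn2 <- genotype_site(c(A = 27, C = 3), ref = "A", mode = "dual")
  expect_lt(gn2$qual, 50)
})

test_that("single-mode posterior matches brute-force binomial enumeration", {
  counts <- c(C = 15, T = 15)
  gs <- genotype_site(counts, ref = "C", mode = "single", error_rate = 0.002)
  expect_equal(sort(gs$genotype), c("C", "T"))
  # independent enumeration over the three genotypes
  e <- 0.002
  p_base <- function(b, g) mean(ifelse(g == b, 1 - e, e / 3))
  lik <- function(g) p_base("C", g)^15 * p_base("T", g)^15
  liks <- c("C/C" = lik(c("C", "C")), "C/T" = lik(c("C", "T")),
            "T/T" = lik(c("T", "T")))
  post <- liks / sum(liks)
  expect_equal(unname(gs$posterior["C/T"]), unname(post["C/T"]), tolerance = 1e-9)
  expect_equal(unname(gs$posterior["C/C"]), unname(post["C/C"]), tolerance = 1e-9)
})

test_that("depth filters mark shallow calls and min_depth is < 2 by default", {
  g <- fx_snp_genome()
  tr <- spike_somatic(g, 25, indel_fraction = 0, seed = 41)
  ov <- apply_mutations(g, tr)
  reads <- simulate_reads(g, 4, overlay = ov, seed = 42) # very low coverage
  dual <- c(g$hapA, g$hapB)
  pl <- pileup(map_reads(reads, dual), dual)
  calls <- call_somatic(pl, "dual", genome = g)
  expect_true(all(calls$depth[grepl("LOWDEPTH", calls$filter)] < 2))
  expect_true(all(calls$depth[!grepl("LOWDEPTH", calls$filter)] >= 2))
})

test_that("a spiked SNP in a divergent region yields one haplotype-resolved call", {
  g <- fx_snp_genome()
  tr <- spike_somatic(g, 30, indel_fraction = 0, seed = 43)
  ov <- apply_mutations(g, tr)
  reads <- simulate_reads(g, 35, overlay = ov, seed = 44)
  dual <- c(g$hapA, g$hapB)
  pl <- pileup(map_reads(reads, dual), dual)
  calls <- call_somatic(pl, "dual", genome = g)
  ret <- retained(calls)
  key_t <- paste(tr$contig, tr$pos, tr$alt)
  key_c <- paste(ret$contig, ret$pos, ret$alt)
  hits <- key_t %in% key_c
  expect_gte(mean(hits), 0.9)
  matched <- ret[key_c %in% key_t, ]
  expect_true(all(matched$alt_count / matched$depth > 0.8 | matched$shared))
})

test_that("mutation-free single-reference calling shows the het background", {
  g <- fx_snp_genome()
  reads <- simulate_reads(g, 35, seed = 45)
  pl <- pileup(map_reads(reads, g$hapA), g$hapA)
  # genotype the germline sites directly: het across the board
  cm <- pl$counts[["chr1_A"]]
  snp <- g$germline[g$germline$kind == "SNP", ][1:50, ]
  het <- vapply(seq_len(nrow(snp)), function(i) {
    cnt <- setNames(cm[, snp$posA[i] + 1], c("A", "C", "G", "T"))
    gs <- genotype_site(cnt, ref = snp$refA[i], mode = "single")
    setequal(gs$genotype, c(snp$refA[i], snp$altB[i]))
  }, logical(1))
  expect_gte(mean(het), 0.95)
  # and the somatic caller reports (almost) none of them as somatic
  calls <- call_somatic(pl, "single", genome = g)
  expect_lte(sum(retained(calls)$kind == "SNP"), 5)
})

test_that("flanking-homology dedup merges only identical contexts and is
           idempotent", {
  # two haplotypes identical except for one divergent zone in the middle
  s <- random_seq(12000, seed = 50)
  zone <- random_seq(400, seed = 51)
  hapA <- c(z_A = s)
  hapB <- c(z_B = paste0(substring(s, 1, 6000), zone, substring(s, 6401)))
  hm <- build_homology_map(hapA, hapB)
  mk_call <- function(contig, pos, hap, ref, alt) {
    data.frame(mode = "dual", haplotype = hap, contig = contig, pos = pos,
               ref = ref, alt = alt, kind = "SNP", genotype = "M", shared = TRUE,
               qual = 99, gq = 99, depth = 30, alt_count = 15,
               dup_group = NA_integer_, hom_pos = NA_character_,
               filter = "PASS", stringsAsFactors = FALSE)
  }
  base_at <- function(seq, pos) substring(seq, pos + 1, pos + 1)
  # identical context at 2000: calls on both haplotypes collapse to one
  c1 <- rbind(mk_call("z_A", 2000, "A", base_at(s, 2000), "T"),
              mk_call("z_B", 2000, "B", base_at(s, 2000), "T"))
  d1 <- dedup_homologous(c1, hapA, hapB, hm)
  expect_equal(sum(d1$filter == "PASS"), 1)
  expect_equal(d1$contig[d1$filter == "PASS"], "z_A") # haplotype A kept
  expect_equal(sum(grepl("DUP", d1$filter)), 1)
  expect_equal(d1$dup_group[1], d1$dup_group[2])
  # divergent context: both calls kept
  c2 <- rbind(mk_call("z_A", 6100, "A", base_at(s, 6100), "T"),
              mk_call("z_B", 6100, "B", base_at(hapB[[1]], 6100), "T"))
  d2 <- dedup_homologous(c2, hapA, hapB, hm)
  expect_equal(sum(d2$filter == "PASS"), 2)
  # idempotence
  expect_identical(dedup_homologous(d1, hapA, hapB, hm), d1)
  expect_identical(dedup_homologous(d2, hapA, hapB, hm), d2)
})

test_that("an engineered duplication concentrates the blacklist and
           blacklisted positions are removed from call sets", {
  # haplotypes whose B copy carries a near-identical 4-kb duplicated segment
  s <- random_seq(30000, seed = 60)
  seg <- substring(s, 10001, 14000)
  hapA <- c(d_A = s)
  hapB <- c(d_B = paste0(substring(s, 1, 24000), seg, substring(s, 24001)))
  g <- structure(list(hapA = hapA, hapB = hapB,
                      homology = build_homology_map(hapA, hapB),
                      germline = data.frame(contig = character(),
                                            kind = character(),
                                            posA = integer(), posB = integer(),
                                            refA = character(),
                                            altB = character(),
                                            length = integer(),
                                            stringsAsFactors = FALSE),
                      seed = 61), class = "diploid_genome")
  bl <- build_blacklist(g, "single", coverage = 30, seed = 62)
  skip_if(nrow(bl) == 0, "no artifacts called under this seed")
  # artifact positions concentrate in and immediately around the duplicated
  # source segment (junction-spanning reads leak shifted alleles at its
  # edges; the identical interior produces no conflicting alleles)
  expect_gte(mean(bl$pos >= 10000 - 200 & bl$pos < 14000 + 200), 0.9)
  fake <- data.frame(mode = "single", haplotype = NA, contig = bl$contig[1],
                     pos = bl$pos[1], ref = "A", alt = "C", kind = "SNP",
                     genotype = "A/C", shared = FALSE, qual = 99, gq = 99,
                     depth = 30, alt_count = 15, dup_group = NA_integer_,
                     hom_pos = NA_character_, filter = "PASS",
                     stringsAsFactors = FALSE)
  out <- apply_blacklist(fake, bl)
  expect_equal(out$filter, "BLACKLIST")
})

test_that("VCF records round-trip losslessly", {
  g <- fx_snp_genome()
  tr <- spike_somatic(g, 20, seed = 71)
  ov <- apply_mutations(g, tr)
  reads <- simulate_reads(g, 30, overlay = ov, seed = 72)
  dual <- c(g$hapA, g$hapB)
  calls <- call_somatic(pileup(map_reads(reads, dual), dual), "dual", genome = g)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(calls, f1, names(dual), nchar(dual))
  back <- read_vcf(f1)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$filter, calls$filter)
  expect_equal(back$depth, calls$depth)
  # write the parsed set again: bytes identical
  write_vcf(back, f2, names(dual), nchar(dual))
  expect_identical(readLines(f1), readLines(f2))
})
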