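# minimal call-set constructor for population-level tests
mk_calls <- function(contig, pos, ref = "A", alt = "T") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# truth-driven population: genotype matrix straight from a simulated clone
# tree, bypassing read simulation
fx_population <- function(n_ingroup = 8, n_outgroup = 3, per_branch = 12,
                          seed = 101) {
  g <- fx_snp_genome()
  tree <- balanced_clone_tree(n_ingroup, n_outgroup)
  pop <- simulate_clonal_population(g, tree, per_branch * nrow(tree$edges),
                                    reads = FALSE, seed = seed)
  call_sets <- lapply(pop$leaf_mutations, function(ids) {
    tt <- pop$truth[pop$truth$id %in% ids, ]
    mk_calls(tt$contig, tt$pos, tt$ref, tt$alt)
  })
  pm <- merge_population(call_sets)
  list(pm = pm, pop = pop, tree = tree)
}

test_that("a single accession's map equals its call set", {
  cs <- mk_calls("chr1_A", c(10, 20, 30), "A", c("C", "G", "T"))
  pm <- merge_population(list(acc1 = cs))
  expect_equal(nrow(pm$geno), 3)
  expect_true(all(pm$geno == 1))
})

test_that("accessions sharing no mutations give a block-diagonal map", {
  pm <- merge_population(list(a = mk_calls("chr1_A", 1:5 * 10),
                              b = mk_calls("chr1_A", 1:5 * 10 + 1)))
  expect_equal(sum(pm$geno[, "a"] > 0 & pm$geno[, "b"] > 0), 0)
})

test_that("conflicting reference alleles are a hard error and no-calls are NA", {
  expect_error(merge_population(list(a = mk_calls("c", 5, ref = "A"),
                                     b = mk_calls("c", 5, ref = "G"))),
               "reference")
  pm <- merge_population(list(a = mk_calls("c", c(5, 9)),
                              b = mk_calls("c", 5)),
                         nocall = list(b = data.frame(contig = "c", pos = 9)))
  expect_true(is.na(pm$geno["c:9:A:T", "b"]))
  expect_equal(pm$geno["c:9:A:T", "a"], 1L)
})

test_that("per-variant occupancy equals clone-tree branch leaf counts", {
  fx <- fx_population()
  pm <- fx$pm; pop <- fx$pop; tree <- fx$tree
  # oracle: a branch's mutations occur in exactly the leaves below it
  leaves_below <- function(branch) {
    names(Filter(function(ids) any(pop$truth$id[pop$truth$branch == branch]
                                   %in% ids), pop$leaf_mutations))
  }
  occ <- rowSums(pm$geno > 0, na.rm = TRUE)
  for (b in unique(pop$truth$branch)) {
    ids <- pop$truth$id[pop$truth$branch == b]
    keys <- paste(pop$truth$contig[match(ids, pop$truth$id)],
                  pop$truth$pos[match(ids, pop$truth$id)],
                  pop$truth$ref[match(ids, pop$truth$id)],
                  pop$truth$alt[match(ids, pop$truth$id)], sep = ":")
    nl <- sum(vapply(pop$leaf_mutations, function(x) ids[1] %in% x, logical(1)))
    expect_true(all(occ[keys] == nl), info = b)
  }
})

test_that("binomial window filter keeps a uniform map and removes loaded
           windows", {
  # null calibration over 20 seeds
  removed_frac <- vapply(1:20, function(sd) {
    pos <- withr::with_seed(sd, sort(sample(0:1999999, 2000)))
    pm <- merge_population(list(a = mk_calls("c_A", pos)))
    w <- binomial_window_filter(pm, c(c_A = 2e6), alpha = 0.001)$windows
    mean(w$removed)
  }, numeric(1))
  expect_lte(mean(removed_frac), 0.001)
  # a window with 10x the uniform expectation is always removed
  for (sd in 1:5) {
    base_pos <- withr::with_seed(sd, sort(sample(0:1999999, 2000)))
    hot <- withr::with_seed(sd + 100, sample(100000:149999, 500))
    pm <- merge_population(list(a = mk_calls("c_A", unique(c(base_pos, hot)))))
    res <- binomial_window_filter(pm, c(c_A = 2e6), alpha = 0.001)
    w <- res$windows
    expect_true(w$removed[w$start == 100000])
    expect_false(any(res$map$variants$pos >= 100000 &
                       res$map$variants$pos < 150000))
  }
})

test_that("outgroup polarization reproduces the brute-force spectrum", {
  fx <- fx_population(n_ingroup = 8, n_outgroup = 3, seed = 103)
  pm <- fx$pm; pop <- fx$pop; tree <- fx$tree
  sp <- polarize_and_spectrum(pm, tree$outgroup)
  # conservation
  expect_equal(sum(sp$spectrum) + sp$unresolved, nrow(pm$geno))
  # brute force from the truth: ancestral allele = absent in all outgroup
  ing <- setdiff(tree$leaves, tree$outgroup)
  truth_occ <- integer(0)
  for (i in seq_len(nrow(pop$truth))) {
    id <- pop$truth$id[i]
    carriers <- names(Filter(function(x) id %in% x, pop$leaf_mutations))
    og_carry <- intersect(carriers, tree$outgroup)
    if (length(og_carry) == 0) {
      truth_occ <- c(truth_occ, length(intersect(carriers, ing)))
    } else if (length(og_carry) == length(tree$outgroup)) {
      truth_occ <- c(truth_occ, length(ing) - length(intersect(carriers, ing)))
    } # else polymorphic in outgroup -> unresolved
  }
  oracle <- tabulate(truth_occ + 1L, nbins = length(ing) + 1L)
  names(oracle) <- 0:length(ing)
  expect_equal(sp$spectrum, oracle)
  # low-frequency definition: occupancy < 3 among carriers of the derived allele
  lf <- sum(truth_occ > 0 & truth_occ < 3) / sum(truth_occ > 0)
  expect_equal(sp$low_freq_fraction, lf)
})

test_that("group-specific screen returns exactly the private branch mutations", {
  fx <- fx_population(n_ingroup = 8, n_outgroup = 3, seed = 105)
  pm <- fx$pm; pop <- fx$pop; tree <- fx$tree
  # choose an internal branch with >= 2 leaves below as the "group"
  for (grp_size in c(2, 4)) {
    grp <- paste0("acc", seq_len(grp_size))
    g <- pm$geno[, grp, drop = FALSE]
    res <- group_specific_screen(pm, grp)
    # oracle: mutations carried by all group members and nobody else
    oracle <- character(0)
    for (i in seq_len(nrow(pop$truth))) {
      id <- pop$truth$id[i]
      carriers <- names(Filter(function(x) id %in% x, pop$leaf_mutations))
      if (setequal(carriers, grp)) oracle <- c(oracle, id)
    }
    keys_res <- paste(res$contig, res$pos)
    tt <- pop$truth[match(oracle, pop$truth$id), ]
    expect_setequal(keys_res, paste(tt$contig, tt$pos))
  }
  # partial presence is excluded by the strict screen, included by relaxed
  two_of_three <- merge_population(list(
    a = mk_calls("c", c(1, 5)), b = mk_calls("c", c(1, 5)),
    c = mk_calls("c", 1), d = mk_calls("c", 99)))
  strict <- group_specific_screen(two_of_three, c("a", "b", "c"))
  expect_false(5 %in% strict$pos)
  expect_true(1 %in% strict$pos)
  relaxed <- group_specific_screen(two_of_three, c("a", "b", "c"),
                                   relaxed = TRUE)
  expect_true(5 %in% relaxed$pos)
})

test_that("screen proximity annotation matches gene bodies and 3-kb flanks", {
  ann <- fx_annotation(n_genes = 5, len = 60000, seed = 77)
  gn <- ann$genes[1, ]
  pos_in <- gn$start + 10
  pos_flank <- gn$start - 2000
  # a position more than 3 kb away from every placed gene
  cand <- setdiff(seq(0, 59999, by = 97), unlist(lapply(
    seq_len(nrow(ann$genes)), function(i)
      (ann$genes$start[i] - 3100):(ann$genes$end[i] + 3100))))
  pos_far <- cand[1]
  pm <- merge_population(list(a = mk_calls(gn$contig, c(pos_in, pos_flank, pos_far)),
                              b = mk_calls(gn$contig, 59000)))
  res <- group_specific_screen(pm, "a", annotation = ann, proximity = 3000)
  expect_equal(res$genes[res$pos == pos_in], gn$gene_id)
  expect_equal(res$genes[res$pos == pos_flank], gn$gene_id)
  expect_true(is.na(res$genes[res$pos == pos_far]))
})

test_that("allele-sharing distances match hand-computed Hamming values and
           the NEXUS block round-trips", {
  geno <- matrix(c(1, 0, 1, 0,
                   1, 1, 0, NA,
                   0, 0, 1, 0), nrow = 4,
                 dimnames = list(paste0("v", 1:4), c("x", "y", "z")))
  pm <- structure(list(geno = geno,
                       variants = data.frame(contig = "c", pos = 1:4,
                                             ref = "A", alt = "T"),
                       accessions = c("x", "y", "z")),
                  class = "population_map")
  d <- export_distance_nexus(pm)
  expect_equal(d["x", "y"], 2 / 3)  # sites 1..3 comparable, 2 mismatches
  expect_equal(d["x", "z"], 1 / 4)  # all 4 comparable, 1 mismatch
  expect_equal(d["y", "z"], 1)      # sites 1..3 comparable, all differ
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality
  expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
  f <- tempfile(fileext = ".nex")
  export_distance_nexus(pm, f)
  back <- read_nexus_distances(f)
  expect_equal(back, d, tolerance = 1e-9)
  # identical accessions are at distance zero
  pm2 <- merge_population(list(p = mk_calls("c", 1:5), q = mk_calls("c", 1:5),
                               r = mk_calls("c", 11:15)))
  d2 <- export_distance_nexus(pm2)
  expect_equal(d2["p", "q"], 0)
})
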