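#' Configuration for the synthetic diploid genome generator
#'
#' The generator produces haplotype A as random sequence (optionally as a
#' mosaic of two divergent donor genomes) and derives haplotype B from it by
#' sampling germline heterozygous SNPs, short InDels and large
#' haplotype-specific segments. Rates are per base pair of aligned (non
#' haplotype-specific) sequence.
#'
#' @param contig_lengths named integer vector of contig lengths (>= 10 kb)
#' @param snp_rate heterozygous SNP rate per bp in aligned regions
#' @param indel_rate heterozygous short-InDel rate per bp
#' @param indel_geom_p geometric length parameter for germline InDels
#' @param indel_max maximum germline InDel length (bp)
#' @param hap_specific_per_mb number of large haplotype-specific segments per
#'   Mb of contig (split evenly between the two haplotypes)
#' @param hap_specific_mean_len mean segment length (exponential), bp
#' @param hap_specific_min_len minimum segment length, bp (SV size floor)
#' @param identical_segments optional integer vector of segment lengths that
#'   are forced to be identical between the haplotypes (no germline variation
#'   sampled inside them); used to engineer regions where short reads cannot
#'   distinguish the two copies
#' @param ancestry optional list(`donor_divergence`, `block_mean_len`): build
#'   haplotype A as a mosaic of two donor genomes ("P" and "M") that diverge
#'   at the given substitution rate, with exponentially distributed ancestry
#'   block lengths
#' @param seed master seed
#' @return a list of class `genome_config`
#' @export
genome_config <- function(contig_lengths = c(chr1 = 200000),
                          snp_rate = 0.018,
                          indel_rate = 0.0018,
                          indel_geom_p = 0.35,
                          indel_max = 50,
                          hap_specific_per_mb = 10,
                          hap_specific_mean_len = 5000,
                          hap_specific_min_len = 50,
                          identical_segments = NULL,
                          ancestry = NULL,
                          seed = 1) {
  if (any(contig_lengths < 10000)) stop("contig lengths must be >= 10 kb")
  if (snp_rate < 0 || snp_rate >= 0.75)
    stop("snp_rate must be in [0, 0.75): rates at or above 3/4 are saturated ",
         "under the equal-rate (Jukes-Cantor) substitution model")
  if (indel_rate < 0 || indel_rate >= 0.75) stop("indel_rate must be in [0, 0.75)")
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  structure(list(contig_lengths = contig_lengths, snp_rate = snp_rate,
                 indel_rate = indel_rate, indel_geom_p = indel_geom_p,
                 indel_max = indel_max,
                 hap_specific_per_mb = hap_specific_per_mb,
                 hap_specific_mean_len = hap_specific_mean_len,
                 hap_specific_min_len = hap_specific_min_len,
                 identical_segments = identical_segments,
                 ancestry = ancestry, seed = seed),
            class = "genome_config")
}

#' Sweet-orange-like genome preset
#'
#' Heterozygosity preset modelled on a highly heterozygous interspecific
#' hybrid: about 18 heterozygous SNPs per kb in aligned regions, short het
#' InDels at roughly one tenth of the SNP density, and large
#' haplotype-specific segments (>= 50 bp) totalling a few percent of each
#' haplotype.
#'
#' @inheritParams genome_config
#' @param ... passed through to [genome_config()]
#' @export
so_genome_config <- function(contig_lengths = c(chr1 = 1000000), seed = 1, ...) {
  genome_config(contig_lengths = contig_lengths, snp_rate = 0.018,
                indel_rate = 0.0018, hap_specific_per_mb = 10,
                hap_specific_mean_len = 5000, seed = seed, ...)
}

# substitute each selected base by a uniformly chosen different base
random_substitutions <- function(bases) {
  alt <- character(length(bases))
  for (b in BASES) {
    i <- which(bases == b)
    if (length(i)) alt[i] <- sample(setdiff(BASES, b), length(i), replace = TRUE)
  }
  alt
}

# greedy non-overlap filter over 0-based [start, start+span) events
keep_nonoverlapping <- function(start, span, L, gap = 2L) {
  ord <- order(start)
  keep_ord <- logical(length(ord))
  last_end <- -10
  for (j in seq_along(ord)) {
    i <- ord[j]
    s <- start[i]; e <- s + span[i]
    if (s <= last_end + gap || s < 1 || e >= L - 1) next
    keep_ord[j] <- TRUE
    last_end <- e
  }
  sort(ord[keep_ord])
}

in_spans <- function(pos, start, end) {
  if (!length(start)) return(rep(FALSE, length(pos)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  i <- findInterval(pos, start)
  i > 0 & pos < end[pmax(i, 1L)]
}

#' Generate a synthetic diploid genome with full ground truth
#'
#' Haplotype B is derived from haplotype A by applying sampled germline
#' heterozygous variants; the exact homology map between the two haplotypes
#' is recorded as the variants are applied. Contig names carry an `_A` /
#' `_B` haplotype suffix and are unique across the combined dual reference.
#'
#' @param config a [genome_config()]
#' @return a list of class `diploid_genome` with elements `hapA`, `hapB`
#'   (named character vectors), `homology` (truth [homology_map()]),
#'   `germline` (data frame of heterozygous variants, anchored VCF-style for
#'   InDels), `ancestry` (data frame of donor blocks or `NULL`), `donors`
#'   (named list of donor genomes or `NULL`), `config`, `seed`
#' @export
generate_diploid <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  seed <- child_seed(config$seed, "generate_diploid")
  hapA <- character(0); hapB <- character(0)
  donors <- NULL
  germ_all <- list(); blocks_all <- list(); gaps_all <- list(); anc_all <- list()
  with_seed(seed, {
    for (ci in seq_along(config$contig_lengths)) {
      ctg <- names(config$contig_lengths)[ci]
      L <- as.integer(config$contig_lengths[ci])
      cA <- paste0(ctg, "_A"); cB <- paste0(ctg, "_B")

      if (is.null(config$ancestry)) {
        A <- random_dna(L)
        anc <- NULL
      } else {
        dP <- random_dna(L)
        nmut <- rbinom(1, L, config$ancestry$donor_divergence)
        mpos <- sort(sample.int(L, nmut)) - 1L
        mref <- strsplit(substring(dP, mpos + 1, mpos + 1), "")
        mref <- vapply(mref, `[`, character(1), 1)
        dM <- substitute_bases(dP, mpos, random_substitutions(mref))
        if (is.null(donors)) donors <- list(P = character(0), M = character(0))
        donors$P[ctg] <- dP; donors$M[ctg] <- dM
        # ancestry mosaic for haplotype A
        bl <- pmax(1000, round(rexp(ceiling(4 * L / config$ancestry$block_mean_len),
                                    1 / config$ancestry$block_mean_len)))
        ends <- cumsum(bl); ends <- c(ends[ends < L], L)
        starts <- c(0, head(ends, -1))
        donor_lab <- sample(c("P", "M"), length(starts), replace = TRUE)
        pieces <- character(length(starts))
        for (j in seq_along(starts)) {
          src <- if (donor_lab[j] == "P") dP else dM
          pieces[j] <- substring(src, starts[j] + 1, ends[j])
        }
        A <- paste(pieces, collapse = "")
        anc <- data.frame(haplotype_id = "A", contig = ctg, start = starts,
                          end = ends, donor = donor_lab, stringsAsFactors = FALSE)
      }

      # ---- structural events on haplotype A coordinates -------------------
      nseg <- round(config$hap_specific_per_mb * L / 1e6)
      seg_len <- if (nseg > 0)
        pmax(config$hap_specific_min_len,
             round(rexp(nseg, 1 / config$hap_specific_mean_len))) else integer(0)
      seg_side <- rep_len(c("A", "B"), nseg) # A-specific (missing in B) or B-specific
      nind <- rbinom(1, L, config$indel_rate)
      ind_len <- pmin(config$indel_max, 1L + rgeom(nind, config$indel_geom_p))
      ind_kind <- sample(c("INS", "DEL"), nind, replace = TRUE)

      ev <- data.frame(
        kind = c(ifelse(seg_side == "A", "SEG_A", "SEG_B"), ind_kind),
        len = c(seg_len, ind_len),
        stringsAsFactors = FALSE)
      # A-span consumed by each event: deletions-from-B consume their length
      ev$spanA <- ifelse(ev$kind %in% c("SEG_A", "DEL"), ev$len, 1L)
      ev$start <- sample.int(L - 2L, nrow(ev), replace = TRUE)
      keep <- keep_nonoverlapping(ev$start, ev$spanA, L)
      ev <- ev[keep, , drop = FALSE]

      # identical segments: carve out windows with no germline variation
      idseg <- NULL
      if (!is.null(config$identical_segments) && length(config$identical_segments)) {
        ids <- as.integer(config$identical_segments)
        st <- sample.int(max(1L, L - max(ids) - 2L), length(ids), replace = TRUE)
        ki <- keep_nonoverlapping(st, ids, L, gap = 500L)
        idseg <- data.frame(start = st[ki], end = st[ki] + ids[ki])
        drop <- vapply(seq_len(nrow(ev)), function(i)
          any(ev$start[i] < idseg$end + 2L &
                ev$start[i] + ev$spanA[i] > idseg$start - 2L), logical(1))
        ev <- ev[!drop, , drop = FALSE]
      }

      # SNPs in aligned regions, outside structural spans
      nsnp <- rbinom(1, L, config$snp_rate)
      spos <- unique(sample.int(L, nsnp, replace = TRUE) - 1L)
      bad <- in_spans(spos, ev$start - 1L, ev$start + ev$spanA + 1L)
      if (!is.null(idseg)) bad <- bad | in_spans(spos, idseg$start, idseg$end)
      spos <- sort(spos[!bad])

      # ---- build haplotype B, homology blocks and germline records --------
      sref <- if (length(spos))
        vapply(strsplit(substring(A, spos + 1, spos + 1), ""), `[`,
               character(1), 1) else character(0)
      salt <- if (length(spos)) random_substitutions(sref) else character(0)
      Bt <- if (length(spos)) substitute_bases(A, spos, salt) else A # B template

      ev <- ev[order(ev$start), , drop = FALSE]
      germ <- list(); blocks <- list(); gaps <- list(); chunks <- list()
      aCur <- 0L   # A cursor (0-based), start of the open block
      bCur <- 0L   # B length emitted so far
      nb <- 0L
      for (j in seq_len(nrow(ev) + 1L)) {
        is_last <- j > nrow(ev)
        p0 <- if (is_last) L else ev$start[j]
        kind <- if (is_last) NA else ev$kind[j]
        # the open block extends to p0 (plus the anchor base for insertions)
        incl <- if (!is_last && kind %in% c("INS", "SEG_B")) 1L else 0L
        a1 <- p0 + incl
        if (a1 > aCur) {
          chunks[[length(chunks) + 1L]] <- substring(Bt, aCur + 1L, a1)
          nb <- nb + 1L
          blocks[[nb]] <- data.frame(contig = ctg, a0 = aCur, a1 = a1,
                                     b0 = bCur, b1 = bCur + (a1 - aCur),
                                     stringsAsFactors = FALSE)
          bCur <- bCur + (a1 - aCur)
        }
        if (is_last) break
        len <- ev$len[j]
        if (kind %in% c("DEL", "SEG_A")) {
          # haplotype B lacks A[p0, p0+len)
          gaps[[length(gaps) + 1L]] <- data.frame(
            contig = ctg, side = "A", start = p0, end = p0 + len,
            other_pos = bCur, hap_specific = kind == "SEG_A",
            stringsAsFactors = FALSE)
          if (kind == "DEL") {
            anchor <- p0 - 1L
            germ[[length(germ) + 1L]] <- data.frame(
              contig = ctg, kind = "DEL", posA = anchor,
              posB = bCur - 1L,
              refA = substring(A, anchor + 1L, anchor + 1L + len),
              altB = substring(A, anchor + 1L, anchor + 1L),
              length = len, stringsAsFactors = FALSE)
          } else {
            germ[[length(germ) + 1L]] <- data.frame(
              contig = ctg, kind = "HAP_SPECIFIC_SEGMENT", posA = p0,
              posB = bCur, refA = NA_character_, altB = NA_character_,
              length = len, stringsAsFactors = FALSE)
          }
          aCur <- p0 + len
        } else { # INS or SEG_B: haplotype B gains sequence after anchor p0
          inseq <- random_dna(len)
          chunks[[length(chunks) + 1L]] <- inseq
          gaps[[length(gaps) + 1L]] <- data.frame(
            contig = ctg, side = "B", start = bCur, end = bCur + len,
            other_pos = p0 + 1L, hap_specific = kind == "SEG_B",
            stringsAsFactors = FALSE)
          if (kind == "INS") {
            germ[[length(germ) + 1L]] <- data.frame(
              contig = ctg, kind = "INS", posA = p0,
              posB = bCur - 1L,
              refA = substring(A, p0 + 1L, p0 + 1L),
              altB = paste0(substring(A, p0 + 1L, p0 + 1L), inseq),
              length = len, stringsAsFactors = FALSE)
          } else {
            germ[[length(germ) + 1L]] <- data.frame(
              contig = ctg, kind = "HAP_SPECIFIC_SEGMENT", posA = p0 + 1L,
              posB = bCur, refA = NA_character_, altB = NA_character_,
              length = len, stringsAsFactors = FALSE)
          }
          bCur <- bCur + len
          aCur <- p0 + 1L
        }
      }
      B <- paste(unlist(chunks), collapse = "")
      hapA[cA] <- A
      hapB[cB] <- B

      blocks <- do.call(rbind, blocks)
      # SNP records with B coordinates through the block map
      if (length(spos)) {
        bi <- findInterval(spos, blocks$a0)
        inside <- bi > 0 & spos < blocks$a1[bi]
        germ[[length(germ) + 1L]] <- data.frame(
          contig = ctg, kind = "SNP", posA = spos,
          posB = ifelse(inside, spos - blocks$a0[bi] + blocks$b0[bi], NA),
          refA = sref, altB = salt, length = 1L, stringsAsFactors = FALSE)
      }
      germ_all[[ctg]] <- do.call(rbind, germ)
      blocks_all[[ctg]] <- blocks
      gaps_all[[ctg]] <- if (length(gaps)) do.call(rbind, gaps) else NULL
      if (!is.null(anc)) {
        anc_all[[ctg]] <- rbind(anc, transform(anc, haplotype_id = "B"))
      }
    }
  })
  germline <- do.call(rbind, germ_all)
  if (!is.null(germline)) {
    germline <- germline[order(germline$contig, germline$posA), , drop = FALSE]
    rownames(germline) <- NULL
  }
  hom <- homology_map(do.call(rbind, blocks_all),
                      if (length(gaps_all)) do.call(rbind, Filter(Negate(is.null), gaps_all)) else NULL)
  structure(list(hapA = hapA, hapB = hapB, homology = hom,
                 germline = germline,
                 ancestry = if (length(anc_all)) do.call(rbind, anc_all) else NULL,
                 donors = donors, config = config, seed = config$seed),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("diploid_genome:", length(x$hapA), "contig(s) per haplotype\n")
  cat("  hapA:", sum(nchar(x$hapA)), "bp; hapB:", sum(nchar(x$hapB)), "bp\n")
  tab <- table(x$germline$kind)
  cat("  germline:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Equal-rate (Jukes-Cantor) base-substitution matrix
#'
#' Under the equal-rate assumption every reference base mutates to each of
#' the three alternatives with probability 1/3.
#' @export
jc_matrix <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  structure(list(prob = m, counts = matrix(0L, 4, 4, dimnames = list(BASES, BASES))),
            class = "mutation_matrix")
}

#' Spike heterozygous somatic mutations onto a diploid genome
#'
#' Positions are sampled uniformly over both haplotype sequences; each
#' mutation lands on exactly one haplotype (heterozygous by construction)
#' and, when a clone tree is supplied, on exactly one branch so that
#' mutations accumulate down the tree. Position collisions (within 30 bp of
#' a previous spike on the same haplotype contig, or overlapping a germline
#' InDel) are resolved by resampling, never by overwriting.
#'
#' @param genome a [generate_diploid()] genome
#' @param n_mutations total number of somatic mutations
#' @param tree optional [clone_tree()]; branches are sampled with probability
#'   proportional to their `n_mut` weight
#' @param matrix a `mutation_matrix` giving alt-base probabilities per ref base
#' @param indel_fraction proportion of mutations that are short InDels
#'   (geometric length, p = 0.5, max 20 bp)
#' @param seed seed (defaults to a child of the genome seed)
#' @return data frame of class `somatic_truth`: `id`, `haplotype`, `contig`
#'   (full haplotype contig name), `pos` (0-based on that haplotype), `ref`,
#'   `alt`, `kind`, `branch`
#' @export
spike_somatic <- function(genome, n_mutations, tree = NULL,
                          matrix = jc_matrix(), indel_fraction = 0.1,
                          seed = NULL) {
  stopifnot(inherits(genome, "diploid_genome"), n_mutations >= 0)
  if (is.null(seed)) seed <- child_seed(genome$seed, "spike_somatic")
  seqs <- c(genome$hapA, genome$hapB)
  empty <- data.frame(id = character(), haplotype = character(),
                      contig = character(), pos = integer(), ref = character(),
                      alt = character(), kind = character(),
                      branch = character(), stringsAsFactors = FALSE)
  class(empty) <- c("somatic_truth", "data.frame")
  if (n_mutations == 0) return(empty)
  lens <- nchar(seqs)
  probs <- lens / sum(lens)
  # forbidden spans: germline indel ref spans on A; none needed on B interior
  forb <- genome$germline[genome$germline$kind %in% c("INS", "DEL"), , drop = FALSE]
  with_seed(seed, {
    rows <- list()
    occupied <- lapply(seqs, function(x) integer(0))
    branches <- if (!is.null(tree)) tree$edges$branch_id else NA_character_
    bweights <- if (!is.null(tree)) tree$edges$n_mut else 1
    tries <- 0L
    while (length(rows) < n_mutations && tries < 50L * n_mutations + 1000L) {
      tries <- tries + 1L
      ctg_i <- sample.int(length(seqs), 1L, prob = probs)
      ctg <- names(seqs)[ctg_i]
      L <- lens[ctg_i]
      pos <- sample.int(L - 44L, 1L) + 20L - 1L # 0-based, away from ends
      if (any(abs(occupied[[ctg_i]] - pos) < 30L)) next
      hap <- if (endsWith(ctg, "_A")) "A" else "B"
      base_ctg <- sub("_[AB]$", "", ctg)
      pcol <- if (hap == "A") "posA" else "posB"
      fb <- forb[forb$contig == base_ctg, , drop = FALSE]
      if (nrow(fb) && any(pos >= fb[[pcol]] - 1 & pos <= fb[[pcol]] + fb$length + 1)) next
      is_indel <- runif(1) < indel_fraction
      refbase <- substring(seqs[ctg_i], pos + 1L, pos + 1L)
      if (!refbase %in% BASES) next
      if (!is_indel) {
        alt <- sample(BASES, 1L, prob = matrix$prob[refbase, ])
        ref <- refbase
        kind <- "SNP"
      } else {
        len <- min(20L, 1L + rgeom(1L, 0.5))
        if (runif(1) < 0.5) { # insertion
          ref <- refbase
          alt <- paste0(refbase, random_dna(len))
          kind <- "INS"
        } else {
          if (pos + 1L + len >= L) next
          ref <- substring(seqs[ctg_i], pos + 1L, pos + 1L + len)
          alt <- refbase
          kind <- "DEL"
        }
      }
      branch <- if (!is.null(tree))
        sample(branches, 1L, prob = bweights) else NA_character_
      occupied[[ctg_i]] <- c(occupied[[ctg_i]], pos)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("som", length(rows) + 1L), haplotype = hap, contig = ctg,
        pos = pos, ref = ref, alt = alt, kind = kind, branch = branch,
        stringsAsFactors = FALSE)
    }
    if (length(rows) < n_mutations)
      warning("could only place ", length(rows), " of ", n_mutations,
              " mutations without collisions")
    out <- do.call(rbind, rows)
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("somatic_truth", "data.frame")
    out
  })
}

#' Apply somatic mutations to haplotype sequences
#'
#' @param genome a `diploid_genome`
#' @param truth rows of a `somatic_truth` data frame (positions refer to the
#'   unmutated genome; overlapping mutations are not allowed)
#' @return named character vector of all haplotype contigs with mutations
#'   applied
#' @export
apply_mutations <- function(genome, truth) {
  seqs <- c(genome$hapA, genome$hapB)
  if (!nrow(truth)) return(seqs)
  for (ctg in unique(truth$contig)) {
    tt <- truth[truth$contig == ctg, , drop = FALSE]
    tt <- tt[order(-tt$pos), , drop = FALSE] # apply right-to-left
    s <- seqs[[ctg]]
    for (i in seq_len(nrow(tt))) {
      p <- tt$pos[i]
      stopifnot(substring(s, p + 1, p + nchar(tt$ref[i])) == tt$ref[i])
      s <- paste0(substring(s, 1, p), tt$alt[i],
                  substring(s, p + 1 + nchar(tt$ref[i])))
    }
    seqs[[ctg]] <- s
  }
  seqs
}

#' Simulate paired-end whole-genome sequencing reads
#'
#' Total coverage is interpreted relative to the length of one haplotype and
#' split evenly between the two chromosome copies: each haplotype contig is
#' sequenced at `coverage / 2`, so total simulated bases equal
#' `coverage * len(hapA)` up to rounding (one read pair per contig).
#' Base qualities are constant Q30; substitution errors are injected
#' independently of quality.
#'
#' @param genome a `diploid_genome`, or a named character vector of contig
#'   sequences (then each contig is sequenced at `coverage / 2`)
#' @param coverage total fold coverage (see above)
#' @param read_len read length, bp
#' @param insert insert-size mean and sd, bp
#' @param error_rate per-base substitution error probability
#' @param seed seed (defaults to a child of the genome seed)
#' @param fastq_prefix optional path prefix: writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and a truth-origin TSV `<prefix>_origins.tsv`
#' @param overlay optional named character vector replacing the genome's
#'   sequences (e.g. from [apply_mutations()])
#' @return data frame of read pairs with truth origins (`contig`, 0-based
#'   `pos1`/`pos2`, `strand1`/`strand2`)
#' @export
simulate_reads <- function(genome, coverage, read_len = 150,
                           insert = c(400, 60), error_rate = 0.002,
                           seed = NULL, fastq_prefix = NULL, overlay = NULL) {
  if (inherits(genome, "diploid_genome")) {
    seqs <- if (is.null(overlay)) c(genome$hapA, genome$hapB) else overlay
    if (is.null(seed)) seed <- child_seed(genome$seed, "simulate_reads")
  } else {
    seqs <- genome
    if (is.null(seed)) seed <- 1L
  }
  stopifnot(coverage >= 0)
  if (insert[1] < read_len) stop("insert mean must be >= read length")
  out <- list()
  with_seed(seed, {
    for (ci in seq_along(seqs)) {
      L <- nchar(seqs[[ci]])
      npairs <- round((coverage / 2) * L / (2 * read_len))
      if (npairs == 0) next
      r <- cpp_simulate_reads(seqs[[ci]], as.integer(npairs),
                              as.integer(read_len), insert[1], insert[2],
                              error_rate)
      out[[length(out) + 1L]] <- data.frame(
        id = paste0(names(seqs)[ci], "_p", seq_len(npairs)),
        contig = names(seqs)[ci],
        seq1 = r$seq1, seq2 = r$seq2,
        pos1 = r$pos1, strand1 = r$strand1,
        pos2 = r$pos2, strand2 = r$strand2,
        stringsAsFactors = FALSE)
    }
  })
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), contig = character(), seq1 = character(),
               seq2 = character(), pos1 = integer(), strand1 = integer(),
               pos2 = integer(), strand2 = integer(), stringsAsFactors = FALSE)
  if (!is.null(fastq_prefix)) {
    write_fastq(reads, fastq_prefix)
    write.table(reads[, c("id", "contig", "pos1", "strand1", "pos2", "strand2")],
                paste0(fastq_prefix, "_origins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  reads
}

#' Simulate a clonally propagated accession population
#'
#' Somatic mutations are assigned to clone-tree branches and accumulate from
#' the root down; each leaf accession's genome carries the mutations on its
#' root-to-leaf path, and reads are simulated per accession.
#'
#' @param genome a `diploid_genome`
#' @param tree a [clone_tree()] with at least 2 leaves and >= 1 outgroup leaf
#' @param n_mutations total mutation budget distributed over branches
#'   proportionally to their `n_mut` weights
#' @param coverage,read_len,insert,error_rate read simulation parameters
#' @param reads simulate reads per accession (set `FALSE` to get only the
#'   truth structure, which is much faster)
#' @param fastq_dir optional directory for per-accession FASTQ files
#' @param seed seed
#' @return list with `truth` (all mutations with branch assignment),
#'   `leaf_mutations` (named list: mutation ids per leaf), `reads` (named
#'   list of read data frames, if requested), `tree`
#' @export
simulate_clonal_population <- function(genome, tree, n_mutations,
                                       coverage = 30, read_len = 150,
                                       insert = c(400, 60), error_rate = 0.002,
                                       reads = TRUE, fastq_dir = NULL,
                                       seed = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  if (length(tree$leaves) >= 2 && !length(tree$outgroup))
    stop("tree must declare at least one outgroup leaf")
  if (is.null(seed)) seed <- child_seed(genome$seed, "clonal_population")
  truth <- spike_somatic(genome, n_mutations, tree = tree,
                         seed = child_seed(seed, "spike"))
  leaf_mut <- lapply(setNames(tree$leaves, tree$leaves), function(lf) {
    truth$id[truth$branch %in% leaf_path(tree, lf)]
  })
  read_list <- NULL
  if (reads) {
    read_list <- list()
    for (lf in tree$leaves) {
      overlay <- apply_mutations(genome, truth[truth$id %in% leaf_mut[[lf]], ,
                                               drop = FALSE])
      prefix <- if (!is.null(fastq_dir)) file.path(fastq_dir, lf) else NULL
      read_list[[lf]] <- simulate_reads(genome, coverage, read_len, insert,
                                        error_rate,
                                        seed = child_seed(seed, paste0("reads_", lf)),
                                        fastq_prefix = prefix, overlay = overlay)
    }
  }
  list(truth = truth, leaf_mutations = leaf_mut, reads = read_list, tree = tree)
}
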