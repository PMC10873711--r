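#' Estimate the base-substitution matrix from SNP calls
#'
#' Counts ref-to-alt substitutions on the reference strand as printed in the
#' calls (no pyrimidine collapsing) and normalizes each reference-base row
#' to sum to 1 over the three alternative bases. Rows with no observations
#' fall back to the uniform (equal-rate) 1/3 row with a warning.
#'
#' @param variants data frame with `ref` and `alt` columns (non-SNP rows are
#'   ignored)
#' @return object of class `mutation_matrix` with `prob` (4x4, zero
#'   diagonal, off-diagonal rows summing to 1) and `counts`
#' @export
estimate_mutation_matrix <- function(variants) {
  snp <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
                    variants$ref %in% BASES & variants$alt %in% BASES, ,
                  drop = FALSE]
  if (!nrow(snp)) stop("need at least one SNP to estimate the matrix")
  counts <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  tab <- table(factor(snp$ref, BASES), factor(snp$alt, BASES))
  counts[] <- as.integer(tab)
  prob <- counts
  for (b in BASES) {
    s <- sum(counts[b, ])
    if (s == 0) {
      warning("no observations for reference base ", b,
              "; using the uniform 1/3 row")
      prob[b, ] <- 1 / 3
      prob[b, b] <- 0
    } else {
      prob[b, ] <- counts[b, ] / s
    }
  }
  structure(list(prob = prob, counts = counts), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("base-substitution matrix (rows = ref, off-diagonal rows sum to 1)\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed mismatch proportion p into an estimated substitution
#' distance under the equal-rate model: d = -(3/4) ln(1 - (4/3) p).
#'
#' @param p mismatch proportion(s), 0 <= p < 0.75
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("p must be in [0, 0.75): the equal-rate model saturates at 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

#' Place non-overlapping protein-coding genes on a genome
#'
#' A synthetic single-transcript annotation: each gene gets a single-exon
#' CDS starting with ATG, ending with a stop codon, with premature in-frame
#' stops removed, on a random strand. Used to exercise effect annotation and
#' dN/dS machinery on genomes with known coding structure.
#'
#' @param seqs named character vector of contig sequences (the annotation
#'   edits coding spans in place, so the returned `seqs` must be used)
#' @param n_genes number of genes
#' @param cds_len range of CDS lengths (rounded to multiples of 3)
#' @param promoter_gap minimum spacing between genes, bp
#' @param seed seed
#' @return list of class `gene_annotation`: `genes` (gene_id, contig,
#'   strand, start, end, tss), `cds` (gene_id, contig, start, end), `seqs`
#' @export
synthesize_annotation <- function(seqs, n_genes = 20, cds_len = c(300, 900),
                                  promoter_gap = 4000, seed = 1) {
  with_seed(seed, {
    genes <- list(); cds <- list()
    occupied <- lapply(seqs, function(x) cbind(start = numeric(0), end = numeric(0)))
    placed <- 0L; tries <- 0L
    while (placed < n_genes && tries < 200L * n_genes) {
      tries <- tries + 1L
      ci <- sample.int(length(seqs), 1L)
      ctg <- names(seqs)[ci]
      L <- nchar(seqs[[ci]])
      len <- 3L * round(runif(1, cds_len[1], cds_len[2]) / 3)
      start <- sample.int(L - len - 2L * promoter_gap, 1L) + promoter_gap
      occ <- occupied[[ci]]
      if (nrow(occ) && any(start < occ[, "end"] + promoter_gap &
                             start + len > occ[, "start"] - promoter_gap)) next
      strand <- sample(c("+", "-"), 1L)
      # write a clean ORF into the contig (ATG ... no internal stop ... stop)
      body_len <- len - 6L
      codons <- apply(matrix(sample(BASES, body_len, TRUE), nrow = 3), 2,
                      paste, collapse = "")
      stops <- c("TAA", "TAG", "TGA")
      codons[codons %in% stops] <- "TGG"
      orf <- paste0("ATG", paste(codons, collapse = ""), sample(stops, 1L))
      insert <- if (strand == "+") orf else cpp_revcomp(orf)
      seqs[[ci]] <- paste0(substring(seqs[[ci]], 1, start),
                           insert,
                           substring(seqs[[ci]], start + len + 1))
      placed <- placed + 1L
      gid <- sprintf("gene%03d", placed)
      occupied[[ci]] <- rbind(occ, cbind(start = start, end = start + len))
      genes[[placed]] <- data.frame(
        gene_id = gid, contig = ctg, strand = strand, start = start,
        end = start + len,
        tss = if (strand == "+") start else start + len - 1L,
        stringsAsFactors = FALSE)
      cds[[placed]] <- data.frame(gene_id = gid, contig = ctg, start = start,
                                  end = start + len, stringsAsFactors = FALSE)
    }
    if (placed < n_genes) warning("placed only ", placed, " of ", n_genes, " genes")
    structure(list(genes = do.call(rbind, genes), cds = do.call(rbind, cds),
                   seqs = seqs),
              class = "gene_annotation")
  })
}

#' Read gene models from a GFF3 file
#'
#' Extracts gene and CDS features into the annotation structure used by
#' [annotate_effects()]. Coordinates are converted to 0-based half-open.
#'
#' @param file GFF3 path
#' @param seqs named character vector of the matching genome
#' @export
read_gff3_annotation <- function(file, seqs) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(file)
  gene <- gr[gr$type == "gene"]
  cdsr <- gr[gr$type == "CDS"]
  gid <- if (!is.null(gene$ID)) gene$ID else gene$Name
  genes <- data.frame(
    gene_id = as.character(gid),
    contig = as.character(GenomicRanges::seqnames(gene)),
    strand = as.character(GenomicRanges::strand(gene)),
    start = GenomicRanges::start(gene) - 1L,
    end = GenomicRanges::end(gene),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  parent <- as.character(if (!is.null(cdsr$Parent)) S4Vectors::unstrsplit(cdsr$Parent) else cdsr$ID)
  cds <- data.frame(
    gene_id = sub("\\..*$", "", parent),
    contig = as.character(GenomicRanges::seqnames(cdsr)),
    start = GenomicRanges::start(cdsr) - 1L,
    end = GenomicRanges::end(cdsr),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, cds = cds, seqs = seqs),
            class = "gene_annotation")
}

# precomputed lookup structures for effect annotation
effect_index <- function(ann) {
  lay <- gene_cds_layout(ann)
  list(lay = lay,
       tab = do.call(rbind, lapply(lay, function(l)
         data.frame(key = paste(l$contig, l$gpos), gene = l$gene,
                    idx = seq_along(l$gpos), stringsAsFactors = FALSE))),
       strand_by_gene = vapply(lay, `[[`, character(1), "strand"),
       seq_by_gene = vapply(lay, `[[`, character(1), "cds_seq"))
}

# per-gene CDS genomic positions (transcription order) and spliced sequence
gene_cds_layout <- function(ann) {
  lay <- list()
  for (g in unique(ann$cds$gene_id)) {
    seg <- ann$cds[ann$cds$gene_id == g, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    gpos <- unlist(mapply(seq, seg$start, seg$end - 1L, SIMPLIFY = FALSE))
    ctg <- seg$contig[1]
    strand <- ann$genes$strand[ann$genes$gene_id == g][1]
    seqf <- paste(substring(ann$seqs[[ctg]], seg$start + 1, seg$end),
                  collapse = "")
    if (strand == "-") {
      gpos <- rev(gpos)
      seqf <- cpp_revcomp(seqf)
    }
    lay[[g]] <- list(gene = g, contig = ctg, strand = strand, gpos = gpos,
                     cds_seq = seqf)
  }
  lay
}

severity_order <- c(stop_gain = 1, start_loss = 2, frameshift = 3,
                    stop_loss = 4, missense = 5, inframe_indel = 6,
                    synonymous = 7, noncoding = 8)

#' Annotate coding effects of variants
#'
#' SNPs inside CDS are classified through the standard genetic code as
#' synonymous / missense / stop_gain / stop_loss / start_loss; InDels inside
#' CDS are frameshift (length not a multiple of 3) or inframe_indel.
#' Variants outside any transcript are noncoding. When transcripts overlap,
#' the most severe effect wins. Loss-of-function = stop_gain, frameshift or
#' start_loss.
#'
#' @param variants data frame with `contig`, `pos` (0-based), `ref`, `alt`
#' @param ann a `gene_annotation`
#' @return the variants with `effect`, `gene` and `lof` columns
#' @export
annotate_effects <- function(variants, ann, .index = NULL) {
  if (is.null(.index)) .index <- effect_index(ann)
  tab <- .index$tab
  strand_by_gene <- .index$strand_by_gene
  seq_by_gene <- .index$seq_by_gene
  code <- Biostrings::GENETIC_CODE
  n <- nrow(variants)
  effect <- rep("noncoding", n)
  gene <- rep(NA_character_, n)
  is_snp <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  vkey <- paste(variants$contig, variants$pos)

  classify_snp <- function(gid, ci, alt) {
    strand <- strand_by_gene[gid]
    base_new <- ifelse(strand == "+", alt, chartr("ACGT", "TGCA", alt))
    codon_i <- (ci - 1) %/% 3
    within <- (ci - 1) %% 3
    codon <- substring(seq_by_gene[gid], codon_i * 3 + 1, codon_i * 3 + 3)
    newc <- paste0(substring(codon, 1, within), base_new,
                   substring(codon, within + 2, 3))
    aa_old <- unname(code[codon]); aa_new <- unname(code[newc])
    ifelse(aa_old == aa_new, "synonymous",
           ifelse(aa_new == "*", "stop_gain",
                  ifelse(aa_old == "*", "stop_loss",
                         ifelse(codon_i == 0, "start_loss", "missense"))))
  }

  snp_i <- which(is_snp)
  if (length(snp_i)) {
    m <- match(vkey[snp_i], tab$key)
    hit <- which(!is.na(m))
    if (length(hit)) {
      rows <- snp_i[hit]
      effect[rows] <- classify_snp(tab$gene[m[hit]], tab$idx[m[hit]],
                                   variants$alt[rows])
      gene[rows] <- tab$gene[m[hit]]
      # overlapping transcripts: most severe effect wins
      if (anyDuplicated(tab$key)) {
        dupkeys <- tab$key[duplicated(tab$key)]
        for (r in rows[vkey[rows] %in% dupkeys]) {
          hits <- tab[tab$key == vkey[r], , drop = FALSE]
          effs <- classify_snp(hits$gene, hits$idx, variants$alt[r])
          effect[r] <- effs[which.min(severity_order[effs])]
          gene[r] <- paste(unique(hits$gene), collapse = ",")
        }
      }
    }
  }
  for (i in which(!is_snp)) { # InDels: overlap of the ref span with any CDS
    span0 <- variants$pos[i]; span1 <- variants$pos[i] + nchar(variants$ref[i])
    ov <- ann$cds[ann$cds$contig == variants$contig[i] &
                    ann$cds$start < span1 & ann$cds$end > span0 + 1, , drop = FALSE]
    if (nrow(ov)) {
      indel_len <- abs(nchar(variants$alt[i]) - nchar(variants$ref[i]))
      effect[i] <- if (indel_len %% 3 == 0) "inframe_indel" else "frameshift"
      gene[i] <- paste(unique(ov$gene_id), collapse = ",")
    }
  }
  variants$effect <- effect
  variants$gene <- gene
  variants$lof <- effect %in% c("stop_gain", "frameshift", "start_loss")
  variants
}

# codon/position/alt -> synonymous? precomputed classification
codon_change_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    res <- array(NA, dim = c(64, 3, 4),
                 dimnames = list(codons, NULL, BASES))
    for (cd in codons) for (w in 1:3) for (b in BASES) {
      if (substring(cd, w, w) == b) next
      newc <- cd
      substring(newc, w, w) <- b
      res[cd, w, b] <- code[[cd]] == code[[newc]]
    }
    tab <<- res
    tab
  }
})

#' Synonymous and nonsynonymous opportunity counts of an annotation
#'
#' Counts, over all CDS sites and all three possible single-base changes per
#' site, how many changes are synonymous (S) and nonsynonymous (N).
#'
#' @param ann a `gene_annotation`
#' @return named numeric vector `c(N = ..., S = ...)`
#' @export
opportunity_counts <- function(ann) {
  tab <- codon_change_table()
  lay <- gene_cds_layout(ann)
  N <- 0; S <- 0
  for (l in lay) {
    len <- nchar(l$cds_seq)
    codons <- substring(l$cds_seq, seq(1, len, 3), seq(3, len, 3))
    for (w in 1:3) {
      cls <- tab[codons, w, ] # n_codons x 4
      S <- S + sum(cls, na.rm = TRUE)
      N <- N + sum(!cls, na.rm = TRUE)
    }
  }
  c(N = N, S = S)
}

#' Raw Jukes-Cantor-corrected dN/dS of a variant set
#'
#' Site-counting estimate: observed nonsynonymous and synonymous SNP counts
#' are converted to proportions of the annotation's N and S opportunities,
#' each proportion is Jukes-Cantor corrected, and the ratio is returned.
#' A pseudo-count of 0.5 synonymous observations guards against division by
#' zero (flagged).
#'
#' @param variants annotated variants (or raw variants; annotation applied)
#' @param ann a `gene_annotation`
#' @return list with `N`, `S`, `pN`, `pS`, `dN`, `dS`, `ratio`,
#'   `pseudo_used`
#' @export
dnds_raw <- function(variants, ann, opp = NULL, .index = NULL) {
  if (!"effect" %in% names(variants))
    variants <- annotate_effects(variants, ann, .index = .index)
  if (is.null(opp)) opp <- opportunity_counts(ann)
  N <- sum(variants$effect %in% c("missense", "stop_gain", "stop_loss", "start_loss"))
  S <- sum(variants$effect == "synonymous")
  pseudo <- S == 0
  S_eff <- if (pseudo) 0.5 else S
  pN <- N / opp["N"]; pS <- S_eff / opp["S"]
  dN <- jc_distance(pN); dS <- jc_distance(pS)
  list(N = N, S = S, pN = unname(pN), pS = unname(pS),
       dN = unname(dN), dS = unname(dS),
       ratio = if (dS > 0) unname(dN / dS) else NA_real_,
       pseudo_used = pseudo)
}

#' Simulate neutral genome-wide mutation sets under a substitution matrix
#'
#' Positions are uniform over the genome; alternative bases are drawn from
#' the matrix row of the reference base. Each replicate's raw dN/dS is
#' recorded; the replicate distribution is the neutral expectation used to
#' normalize the observed ratio.
#'
#' @param matrix a `mutation_matrix`
#' @param ann a `gene_annotation` (its `seqs` are the genome)
#' @param n_mutations mutations per replicate
#' @param R number of replicates
#' @param seed seed
#' @return list of class `neutral_sim`: `ratios` (length R), `sets`
#'   (variant data frames), `n_mutations`, `R`
#' @export
simulate_neutral <- function(matrix, ann, n_mutations, R = 100, seed = 1) {
  stopifnot(R >= 2)
  seqs <- ann$seqs
  lens <- nchar(seqs)
  ratios <- numeric(R)
  sets <- vector("list", R)
  idx <- effect_index(ann)
  opp <- opportunity_counts(ann)
  with_seed(seed, {
    for (r in seq_len(R)) {
      ci <- sample.int(length(seqs), n_mutations, replace = TRUE,
                       prob = lens / sum(lens))
      pos <- vapply(ci, function(j) sample.int(lens[j], 1L) - 1L, integer(1))
      ref <- substring(seqs[ci], pos + 1, pos + 1)
      alt <- vapply(ref, function(b)
        sample(BASES, 1L, prob = matrix$prob[b, ]), character(1),
        USE.NAMES = FALSE)
      v <- data.frame(contig = names(seqs)[ci], pos = pos, ref = ref,
                      alt = alt, stringsAsFactors = FALSE)
      v <- annotate_effects(v, ann, .index = idx)
      sets[[r]] <- v
      ratios[r] <- dnds_raw(v, ann, opp = opp)$ratio
    }
  })
  structure(list(ratios = ratios, sets = sets, n_mutations = n_mutations,
                 R = R), class = "neutral_sim")
}

#' Neutral-normalized dN/dS
#'
#' The observed raw dN/dS divided by the mean of the neutral replicate
#' ratios; values above 1 indicate an excess of nonsynonymous change over
#' the mutational opportunity. The uncertainty band transfers the neutral
#' replicate spread: both the replicate standard deviation and the 2.5/97.5
#' percentile interval are reported.
#'
#' @param variants observed variant set
#' @param neutral a [simulate_neutral()] result
#' @param ann a `gene_annotation`
#' @return list of class `dnds_result`
#' @export
normalized_dnds <- function(variants, neutral, ann) {
  obs <- dnds_raw(variants, ann)
  nr <- neutral$ratios[is.finite(neutral$ratios)]
  if (length(nr) < 2 || is.na(obs$ratio)) {
    warning("normalized dN/dS undefined (no synonymous information)")
    return(structure(list(observed = obs, normalized = NA_real_), class = "dnds_result"))
  }
  mu <- mean(nr)
  norm <- obs$ratio / mu
  # nonparametric 95% band from the replicate order statistics: the
  # (k, R+1-k) pair is a valid >= 95% prediction interval for a new neutral
  # ratio (interpolated quantiles systematically under-cover here)
  k <- max(1L, floor((length(nr) + 1) * 0.025))
  srt <- sort(nr)
  ci <- obs$ratio / c(srt[length(nr) + 1L - k], srt[k])
  structure(list(
    observed = obs,
    neutral_mean = mu, neutral_sd = sd(nr),
    normalized = norm,
    normalized_sd = norm * sd(nr) / mu,
    ci95 = ci,
    R = length(nr)), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  if (is.na(x$normalized)) {
    cat("dN/dS: undefined\n")
    return(invisible(x))
  }
  cat(sprintf("normalized dN/dS = %.3f +/- %.3f (95%% interval %.3f-%.3f, R = %d)\n",
              x$normalized, x$normalized_sd, x$ci95[1], x$ci95[2], x$R))
  cat(sprintf("  observed: N = %d, S = %d, raw dN/dS = %.3f\n",
              x$observed$N, x$observed$S, x$observed$ratio))
  invisible(x)
}
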