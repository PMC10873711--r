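#' Genotype one pileup column
#'
#' Maximum-likelihood genotyping under binomial sampling of alleles with a
#' per-base error rate and a flat prior over genotypes.
#'
#' In *single* mode the column comes from a collapsed diploid mapping, and
#' genotypes are unordered allele pairs (ref-hom / het / alt-hom, plus
#' tri-allelic pairs when three alleles are observed). In *dual* mode each
#' haplotype contig represents a single chromosome copy, so columns are
#' expected to be near-monoallelic; hypotheses are a pure allele per observed
#' allele plus a mixed (50:50) state that captures cross-mapping from the
#' homologous copy in regions where the two haplotypes are indistinguishable.
#'
#' `qual` is the Phred-scaled posterior probability of the no-variant
#' (pure-reference / ref-hom) hypothesis — the confidence that the site
#' carries any non-reference allele, which is the quantity the quality filter
#' acts on. `gq` is the Phred-scaled probability that the best genotype is
#' wrong.
#'
#' @param counts named numeric vector of per-allele read counts
#' @param ref name of the reference allele
#' @param mode "single" (diploid) or "dual" (haploid + mixed)
#' @param error_rate per-base error prior
#' @return list with `genotype` (character vector of 1-2 alleles), `mixed`
#'   (dual mode: best state is the 50:50 mix), `qual`, `gq`, `posterior`
#'   (named), `depth`
#' @export
genotype_site <- function(counts, ref, mode = c("single", "dual"),
                          error_rate = 0.002, force = NULL) {
  mode <- match.arg(mode)
  keep <- counts > 0 | names(counts) == ref | names(counts) %in% force
  counts <- counts[keep]
  if (!ref %in% names(counts)) counts <- c(setNames(0, ref), counts)
  depth <- sum(counts)
  stopifnot(depth >= 1)
  alleles <- names(counts)
  # cap at ref + top 3 non-ref alleles (expected/forced alleles always kept)
  nonref <- setdiff(alleles[order(-counts[alleles])], ref)
  alleles <- unique(c(ref, head(nonref, 3), intersect(force, alleles)))
  counts <- counts[alleles]
  counts[is.na(counts)] <- 0
  e <- error_rate
  p_err <- e / 3
  ll_allele <- function(a) { # log P(base | single source allele a), per allele
    log(ifelse(alleles == a, 1 - e, p_err))
  }
  if (mode == "dual") {
    # hypotheses: a pure allele per observed allele; a 50:50 mix of ref and
    # each alt (cross-mapping from an indistinguishable homologous copy);
    # and a low-fraction noise state per alt (residue of locally misaligned
    # reads), which is treated as non-variant. The noise states carry a
    # small prior weight: misaligned-residue columns are rare (~1e-3 of
    # sites, clustered near structural differences), whereas the mixed
    # state is the expected signature of a real mutation wherever the two
    # haplotypes are locally identical
    noise_f <- 0.1
    noise_prior <- 0.01
    hyp <- c(lapply(alleles, function(a) list(name = if (a == ref) "R" else paste0("A:", a),
                                              lp = ll_allele(a), alleles = a,
                                              mixed = FALSE, w = 1)),
             lapply(setdiff(alleles, ref), function(a)
               list(name = paste0("M:", a),
                    lp = log(0.5 * exp(ll_allele(ref)) + 0.5 * exp(ll_allele(a))),
                    alleles = c(ref, a), mixed = TRUE, w = 1)),
             lapply(setdiff(alleles, ref), function(a)
               list(name = paste0("N:", a),
                    lp = log((1 - noise_f) * exp(ll_allele(ref)) + noise_f * exp(ll_allele(a))),
                    alleles = ref, mixed = FALSE, w = noise_prior)))
    refname <- "R"
  } else {
    pairs <- list()
    na <- length(alleles)
    for (i in seq_len(na)) for (j in i:na) {
      a <- alleles[i]; b <- alleles[j]
      pairs[[length(pairs) + 1L]] <- list(
        name = paste(sort(c(a, b)), collapse = "/"),
        lp = log(0.5 * exp(ll_allele(a)) + 0.5 * exp(ll_allele(b))),
        alleles = c(a, b), mixed = FALSE)
    }
    hyp <- pairs
    refname <- paste(ref, ref, sep = "/")
  }
  loglik <- vapply(hyp, function(h) sum(counts * h$lp), numeric(1))
  lw <- vapply(hyp, function(h) log(if (is.null(h$w)) 1 else h$w), numeric(1))
  loglik <- loglik + lw
  post <- exp(loglik - log_sum_exp(loglik))
  names(post) <- vapply(hyp, `[[`, character(1), "name")
  best <- which.max(loglik)
  nonvar <- if (mode == "dual") grepl("^(R$|N:)", names(post)) else
    names(post) == refname | grepl("^N:", names(post))
  list(genotype = hyp[[best]]$alleles,
       name = hyp[[best]]$name,
       mixed = isTRUE(hyp[[best]]$mixed),
       qual = phred(sum(post[nonvar])),
       gq = phred(1 - post[best]),
       posterior = post,
       depth = depth)
}

germline_expected <- function(genome) {
  g <- genome$germline
  g <- g[g$kind %in% c("SNP", "INS", "DEL"), , drop = FALSE]
  g
}

filter_string <- function(lowqual, lowdepth, blacklist) {
  f <- mapply(function(a, b, c) {
    x <- c(if (a) "LOWQUAL", if (b) "LOWDEPTH", if (c) "BLACKLIST")
    if (length(x)) paste(x, collapse = ",") else "PASS"
  }, lowqual, lowdepth, blacklist)
  as.character(f)
}

#' Call somatic variants from a pileup
#'
#' In *dual* mode both haplotypes are in the reference, germline
#' heterozygosity is absorbed into the reference, and any confident
#' non-reference allele on a haplotype contig is a somatic candidate;
#' flanking-homology deduplication then collapses calls made at homologous
#' positions of the two haplotypes. In *single* mode reads from both
#' chromosome copies pile onto haplotype A, and a site is somatic when its
#' called diploid genotype differs from the reference individual's expected
#' genotype (hom-ref away from germline variants, het at them) — so the
#' germline variant set of the reference individual must be supplied via
#' `genome`.
#'
#' @param pl a [pileup()] against the appropriate reference
#' @param mode "dual" or "single"
#' @param genome the reference `diploid_genome` (required in single mode for
#'   the expected germline genotypes; used in dual mode for dedup sequences)
#' @param blacklist optional [build_blacklist()] result
#' @param min_qual quality filter threshold (Phred)
#' @param min_depth depth filter threshold (per pileup column, i.e. per
#'   haplotype in dual mode)
#' @param min_alt minimum supporting reads for a candidate allele
#' @param error_rate per-base error prior
#' @param homology homology map for dual-mode dedup (defaults to the
#'   genome's truth map)
#' @param dedup run flanking-homology deduplication (dual mode)
#' @param flank flank length for deduplication, bp
#' @param blacklist_pad calls within this many bp of a blacklist entry are
#'   also filtered (absorbs InDel-anchor representation jitter)
#' @return data frame of class `somatic_calls`; retained calls have
#'   `filter == "PASS"`
#' @export
call_somatic <- function(pl, mode = c("dual", "single"), genome = NULL,
                         blacklist = NULL, min_qual = 50, min_depth = 2,
                         min_alt = 2, error_rate = 0.002, homology = NULL,
                         dedup = TRUE, flank = 150, blacklist_pad = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(pl, "pileup"))
  if (mode == "single" && is.null(genome))
    stop("single mode requires the reference genome's germline variant set")
  refs <- pl$reference
  rows <- list()
  germ <- if (!is.null(genome)) germline_expected(genome) else NULL

  for (ctg in names(refs)) {
    cm <- pl$counts[[ctg]]
    L <- ncol(cm)
    refcode <- match(strsplit(refs[[ctg]], "")[[1]], BASES)
    valid <- !is.na(refcode)
    depth <- colSums(cm)
    refct <- numeric(L)
    refct[valid] <- cm[cbind(refcode[valid], which(valid))]
    nonref <- depth - refct
    cand <- which(nonref >= min_alt & valid)
    base_ctg <- sub("_[AB]$", "", ctg)
    hap <- if (endsWith(ctg, "_A")) "A" else if (endsWith(ctg, "_B")) "B" else NA
    exp_tab <- NULL
    if (mode == "single" && !is.null(germ)) {
      exp_tab <- germ[germ$contig == base_ctg, , drop = FALSE]
      hetsnp <- exp_tab[exp_tab$kind == "SNP", , drop = FALSE]
      # germline het sites are candidates even without a novel allele:
      # a somatic change can convert het to hom
      cand <- sort(union(cand, hetsnp$posA[hetsnp$posA < L &
                                             depth[hetsnp$posA + 1] >= 1] + 1L))
      # fast pre-screen: a germline het site with clearly balanced ref/alt
      # counts and no third allele is unambiguously the expected genotype
      hp <- hetsnp$posA + 1L
      hp <- hp[hp >= 1 & hp <= L]
      if (length(hp)) {
        altcode <- match(hetsnp$altB[match(hp - 1L, hetsnp$posA)], BASES)
        okh <- !is.na(altcode)
        hc <- hp[okh]; ac <- altcode[okh]
        refn <- refct[hc]
        altn <- cm[cbind(ac, hc)]
        third <- depth[hc] - refn - altn
        clear <- third == 0 & refn >= 0.2 * depth[hc] & altn >= 0.2 * depth[hc] &
          depth[hc] >= 8
        cand <- setdiff(cand, hc[clear])
      }
    }
    for (ci in cand) {
      pos <- ci - 1L
      cnt <- setNames(cm[, ci], BASES)
      refb <- BASES[refcode[ci]]
      if (mode == "dual") {
        gs <- genotype_site(cnt, refb, mode = mode, error_rate = error_rate)
        if (gs$name == "R" || startsWith(gs$name, "N:")) next
        alt <- setdiff(gs$genotype, refb)[1]
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, haplotype = hap, contig = ctg, pos = pos,
          ref = refb, alt = alt, kind = "SNP",
          genotype = gs$name, shared = gs$mixed,
          qual = unname(gs$qual), gq = unname(gs$gq), depth = unname(gs$depth),
          alt_count = unname(cnt[alt]), stringsAsFactors = FALSE)
      } else {
        expected <- c(refb, refb)
        if (!is.null(exp_tab)) {
          m <- exp_tab[exp_tab$kind == "SNP" & exp_tab$posA == pos, , drop = FALSE]
          if (nrow(m)) expected <- c(m$refA[1], m$altB[1])
        }
        gs <- genotype_site(cnt, refb, mode = mode, error_rate = error_rate,
                            force = unique(expected))
        called <- sort(gs$genotype)
        if (identical(called, sort(expected))) next
        novel <- setdiff(called, expected)
        alt <- if (length(novel)) paste(novel, collapse = ",") else "."
        q_som <- phred(gs$posterior[paste(sort(expected), collapse = "/")])
        if (is.na(q_som)) q_som <- 300
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, haplotype = NA_character_, contig = ctg, pos = pos,
          ref = refb, alt = alt, kind = "SNP",
          genotype = paste(called, collapse = "/"), shared = FALSE,
          qual = unname(q_som), gq = unname(gs$gq), depth = unname(gs$depth),
          alt_count = unname(sum(cnt[novel])), stringsAsFactors = FALSE)
      }
    }

    # ---- InDel candidates ----------------------------------------------
    germ_indel_keys <- character(0)
    if (mode == "single" && !is.null(exp_tab)) {
      gm <- exp_tab[exp_tab$kind %in% c("INS", "DEL"), , drop = FALSE]
      if (nrow(gm)) {
        germ_indel_keys <- vapply(seq_len(nrow(gm)), function(gi) {
          z <- normalize_variant(refs[[ctg]], gm$posA[gi], gm$refA[gi], gm$altB[gi])
          paste(z$pos, z$ref, z$alt)
        }, character(1))
      }
    }
    ins <- pl$ins[pl$ins$contig == ctg & pl$ins$count >= min_alt, , drop = FALSE]
    del <- pl$del[pl$del$contig == ctg & pl$del$count >= min_alt, , drop = FALSE]
    indels <- rbind(
      if (nrow(ins)) data.frame(pos = ins$pos, len = nchar(ins$seq),
                                seq = ins$seq, kind = "INS", count = ins$count,
                                stringsAsFactors = FALSE),
      if (nrow(del)) data.frame(pos = del$pos, len = del$len, seq = NA,
                                kind = "DEL", count = del$count,
                                stringsAsFactors = FALSE))
    if (!is.null(indels) && nrow(indels)) {
      for (ii in seq_len(nrow(indels))) {
        p <- indels$pos[ii]
        if (p + 2 > L || p < 0) next
        anchor_base <- substring(refs[[ctg]], p + 1, p + 1)
        if (indels$kind[ii] == "INS") {
          refal <- anchor_base
          altal <- paste0(anchor_base, indels$seq[ii])
        } else {
          refal <- substring(refs[[ctg]], p + 1, p + 1 + indels$len[ii])
          altal <- anchor_base
        }
        altc <- indels$count[ii]
        refc_sup <- max(0, depth[min(L, p + 2)] - if (indels$kind[ii] == "INS") altc else 0)
        cnt <- setNames(c(refc_sup, altc), c(refal, altal))
        gs <- genotype_site(cnt, refal, mode = mode, error_rate = error_rate)
        nv <- normalize_variant(refs[[ctg]], p, refal, altal)
        if (mode == "dual") {
          if (gs$name == "R" || startsWith(gs$name, "N:")) next
          rows[[length(rows) + 1L]] <- data.frame(
            mode = mode, haplotype = hap, contig = ctg, pos = nv$pos,
            ref = nv$ref, alt = nv$alt, kind = indels$kind[ii],
            genotype = if (gs$mixed) "M:INDEL" else "A:INDEL",
            shared = gs$mixed,
            qual = unname(gs$qual), gq = unname(gs$gq),
            depth = unname(gs$depth), alt_count = altc,
            stringsAsFactors = FALSE)
        } else {
          if (gs$name == paste(sort(c(refal, refal)), collapse = "/")) next
          # germline het InDel at this anchor with the same allele?
          if (paste(nv$pos, nv$ref, nv$alt) %in% germ_indel_keys) next
          het <- length(unique(gs$genotype)) > 1
          rows[[length(rows) + 1L]] <- data.frame(
            mode = mode, haplotype = NA_character_, contig = ctg, pos = nv$pos,
            ref = nv$ref, alt = nv$alt, kind = indels$kind[ii],
            genotype = if (het) "REF/INDEL" else "INDEL/INDEL", shared = FALSE,
            qual = unname(gs$qual), gq = unname(gs$gq),
            depth = unname(gs$depth), alt_count = altc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mode = character(), haplotype = character(), contig = character(),
               pos = integer(), ref = character(), alt = character(),
               kind = character(), genotype = character(), shared = logical(),
               qual = numeric(), gq = numeric(), depth = integer(),
               alt_count = integer(), dup_group = integer(),
               hom_pos = character(), filter = character(),
               stringsAsFactors = FALSE)
  if (nrow(calls)) {
    calls$dup_group <- NA_integer_
    calls$hom_pos <- NA_character_
    bl_hit <- rep(FALSE, nrow(calls))
    if (!is.null(blacklist)) {
      bl_hit <- paste(calls$contig, calls$pos) %in%
        blacklist_keys(blacklist, blacklist_pad)
    }
    calls$filter <- filter_string(calls$qual < min_qual, calls$depth < min_depth,
                                  bl_hit)
  }
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("somatic_calls", "data.frame")
  if (mode == "dual" && dedup) {
    if (is.null(homology) && !is.null(genome)) homology <- genome$homology
    if (!is.null(homology) && !is.null(genome)) {
      calls <- dedup_homologous(calls, genome$hapA, genome$hapB, homology,
                                flank = flank)
    }
  }
  calls
}

#' Collapse duplicate calls at homologous positions of the two haplotypes
#'
#' For each call the `flank` bp on either side of the site are compared with
#' the flanks around the homologous position on the other haplotype
#' (truncated symmetrically at contig ends). When both flank pairs are
#' exactly identical the surrounding region cannot be distinguished by
#' short reads, so calls at the two homologous positions are merged into
#' one: the haplotype-A coordinate is kept and the partner is flagged `DUP`.
#' Calls inside homology gaps are left untouched. The operation is
#' idempotent.
#'
#' @param calls dual-mode `somatic_calls`
#' @param hapA,hapB named character vectors of haplotype sequences
#' @param homology a [homology_map()]
#' @param flank flank length, bp
#' @export
dedup_homologous <- function(calls, hapA, hapB, homology, flank = 150) {
  if (!nrow(calls)) return(calls)
  seqs <- c(hapA, hapB)
  grp <- 0L
  key <- paste(calls$contig, calls$pos, calls$alt)
  for (i in seq_len(nrow(calls))) {
    if (grepl("DUP", calls$filter[i])) next
    hap <- calls$haplotype[i]
    if (is.na(hap)) next
    base <- sub("_[AB]$", "", calls$contig[i])
    ppos <- homology_lookup(homology, base, calls$pos[i], from = hap)
    if (is.na(ppos)) next # homology gap: no homolog, keep as is
    other_hap <- if (hap == "A") "B" else "A"
    other_ctg <- paste0(base, "_", other_hap)
    s1 <- seqs[[calls$contig[i]]]
    s2 <- seqs[[other_ctg]]
    if (is.null(s2)) next
    span <- nchar(calls$ref[i])
    p1 <- calls$pos[i]; p2 <- ppos
    lw <- min(flank, p1, p2)
    rw <- min(flank, nchar(s1) - (p1 + span), nchar(s2) - (p2 + span))
    if (lw < 0 || rw < 0) next
    left_same <- substring(s1, p1 - lw + 1, p1) == substring(s2, p2 - lw + 1, p2)
    right_same <- substring(s1, p1 + span + 1, p1 + span + rw) ==
      substring(s2, p2 + span + 1, p2 + span + rw)
    if (!(left_same && right_same)) next
    calls$hom_pos[i] <- paste0(other_ctg, ":", p2)
    partner <- which(calls$contig == other_ctg & calls$pos == p2 &
                       calls$alt == calls$alt[i] & !grepl("DUP", calls$filter))
    if (length(partner)) {
      j <- partner[1]
      if (is.na(calls$dup_group[i]) && is.na(calls$dup_group[j])) {
        grp <- grp + 1L
        calls$dup_group[i] <- grp
        calls$dup_group[j] <- grp
        calls$hom_pos[j] <- paste0(calls$contig[i], ":", p1)
        # keep the haplotype-A coordinate
        drop <- if (hap == "A") j else i
        if (!grepl("DUP", calls$filter[drop])) {
          calls$filter[drop] <- if (calls$filter[drop] == "PASS") "DUP"
                                else paste0(calls$filter[drop], ",DUP")
        }
      }
    }
  }
  void <- key # silence lints; key reserved for future exact matching
  calls
}

#' Build a false-positive blacklist from a mutation-free simulation
#'
#' Reads are simulated from the unmutated genome at the working coverage,
#' mapped and called in the requested mode; every position called variant on
#' this null input is a systematic artifact of the reference structure (e.g.
#' near-identical duplicated sequence) and is blacklisted. Candidate
#' positions are collected with a permissive quality floor so that artifacts
#' fluctuating around the calling threshold are still captured.
#'
#' @param genome a `diploid_genome` (without somatic spikes)
#' @param mode "dual" or "single"
#' @param coverage simulated fold coverage
#' @param read_len,insert,error_rate read simulation parameters
#' @param min_qual quality floor for blacklist membership
#' @param seed seed
#' @param indel_context single mode: blacklist this many bp around every
#'   germline heterozygous InDel (alignment of reads spanning the InDel is
#'   ambiguous there; set 0 to disable)
#' @param ... passed to [map_reads()]
#' @return data frame of class `blacklist` with `contig`, `pos`, `reason`
#' @export
build_blacklist <- function(genome, mode = c("dual", "single"), coverage = 35,
                            read_len = 150, insert = c(400, 60),
                            error_rate = 0.002, min_qual = 20, seed = NULL,
                            indel_context = 10, ...) {
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- child_seed(genome$seed, paste0("blacklist_", mode))
  reads <- simulate_reads(genome, coverage, read_len, insert, error_rate,
                          seed = seed)
  ref <- if (mode == "dual") c(genome$hapA, genome$hapB) else genome$hapA
  aln <- map_reads(reads, ref, mode = mode, insert = insert, ...)
  pl <- pileup(aln, ref)
  calls <- call_somatic(pl, mode = mode, genome = genome, min_qual = min_qual,
                        error_rate = error_rate, dedup = FALSE)
  out <- unique(data.frame(contig = calls$contig, pos = calls$pos,
                           reason = rep("null_sim", nrow(calls)),
                           stringsAsFactors = FALSE))
  # in single mode, reads spanning a germline heterozygous InDel are placed
  # ambiguously around it and leak shifted alleles: the null simulation
  # exposes these sites stochastically, read sampling decides which
  # representation surfaces in any one run, so the whole neighbourhood of
  # every germline InDel is excluded deterministically
  if (mode == "single" && indel_context > 0 && !is.null(genome$germline)) {
    gm <- genome$germline[genome$germline$kind %in% c("INS", "DEL"), ,
                          drop = FALSE]
    if (nrow(gm)) {
      span <- pmax(gm$length, 1L) + indel_context
      ctxt <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i)
        data.frame(contig = paste0(gm$contig[i], "_A"),
                   pos = (gm$posA[i] - indel_context):(gm$posA[i] + span[i]),
                   reason = "germline_indel_context",
                   stringsAsFactors = FALSE)))
      out <- unique(rbind(out, ctxt))
    }
  }
  class(out) <- c("blacklist", "data.frame")
  out
}

# blacklisted (contig, pos) keys, optionally padded by +/- pad bp to absorb
# representation jitter of InDel anchor positions
blacklist_keys <- function(blacklist, pad = 0) {
  unlist(lapply(-pad:pad, function(d) paste(blacklist$contig, blacklist$pos + d)))
}

#' Remove blacklisted positions from a call set
#' @param calls `somatic_calls`
#' @param blacklist a `blacklist`
#' @param pad also match positions within `pad` bp of a blacklist entry
#' @export
apply_blacklist <- function(calls, blacklist, pad = 0) {
  hit <- paste(calls$contig, calls$pos) %in% blacklist_keys(blacklist, pad)
  upd <- hit & !grepl("BLACKLIST", calls$filter)
  calls$filter[upd] <- ifelse(calls$filter[upd] == "PASS", "BLACKLIST",
                              paste0(calls$filter[upd], ",BLACKLIST"))
  calls
}

#' Retained (PASS) calls
#' @param calls `somatic_calls`
#' @export
retained <- function(calls) calls[calls$filter == "PASS", , drop = FALSE]
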