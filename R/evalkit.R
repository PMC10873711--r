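normalize_truth <- function(genome, truth) {
  seqs <- c(genome$hapA, genome$hapB)
  if (!nrow(truth)) {
    truth$npos <- integer(0); truth$nref <- character(0); truth$nalt <- character(0)
    return(truth)
  }
  nv <- lapply(seq_len(nrow(truth)), function(i)
    normalize_variant(seqs[[truth$contig[i]]], truth$pos[i], truth$ref[i],
                      truth$alt[i]))
  truth$npos <- vapply(nv, `[[`, numeric(1), "pos")
  truth$nref <- vapply(nv, `[[`, character(1), "ref")
  truth$nalt <- vapply(nv, `[[`, character(1), "alt")
  truth
}

#' Score a call set against the spiked ground truth
#'
#' Three evaluation assumptions mirror the three mapping strategies:
#' `dual` matches calls by haplotype-resolved position and allele (calls
#' merged or ambiguous between the two copies also match through their
#' homologous partner coordinate, but only a haplotype-resolved match counts
#' as genotype-correct); `single_position` projects haplotype-B truth onto
#' haplotype A through the homology map and matches by position only;
#' `single_genotype` additionally requires the called diploid genotype
#' (including tri-allelic sites at germline heterozygous positions) to equal
#' the truth genotype. Truth positions that cannot be projected (homology
#' gaps) are reported as `unreachable` and count as missed.
#'
#' @param calls `somatic_calls`
#' @param truth `somatic_truth` from [spike_somatic()]
#' @param genome the reference `diploid_genome`
#' @param mode one of "dual", "single_position", "single_genotype"
#' @param coverage recorded in the result (optional)
#' @return one-row data frame: TP/FP/FN counts, recall, precision, F1,
#'   genotype-correct fraction
#' @export
evaluate_calls <- function(calls, truth, genome,
                           mode = c("dual", "single_position", "single_genotype"),
                           coverage = NA) {
  mode <- match.arg(mode)
  truth <- normalize_truth(genome, truth)
  ret <- retained(calls)
  n_truth <- nrow(truth)
  unreachable <- 0L
  if (mode == "dual") {
    ckey <- paste(ret$contig, ret$pos, ret$alt)
    hkey <- ifelse(is.na(ret$hom_pos), NA,
                   paste(sub(":.*", "", ret$hom_pos),
                         sub(".*:", "", ret$hom_pos), ret$alt))
    tkey <- paste(truth$contig, truth$npos, truth$nalt)
    direct <- tkey %in% ckey
    via_partner <- tkey %in% hkey[!is.na(hkey)]
    tp_mask <- direct | via_partner
    # genotype-correct: the call implies the correct heterozygous genotype.
    # A haplotype-resolved call or a merged/ambiguous call both imply one
    # mutated copy; only a failed dedup — both homologous positions retained
    # as separate calls, implying a homozygous change — is a genotype error.
    tbase <- sub("_[AB]$", "", truth$contig)
    tpartner <- homology_lookup_vec(genome$homology, tbase, truth$npos,
                                    truth$haplotype)
    other_hap <- ifelse(truth$haplotype == "A", "B", "A")
    pkey2 <- ifelse(is.na(tpartner), NA,
                    paste(paste0(tbase, "_", other_hap), tpartner, truth$nalt))
    double_called <- direct & !is.na(pkey2) & pkey2 %in% ckey
    geno_ok <- tp_mask & !double_called
    # haplotype-resolved detections (stricter, reported separately)
    res_key <- paste(ret$contig[!ret$shared], ret$pos[!ret$shared],
                     ret$alt[!ret$shared])
    hap_resolved <- sum(tkey %in% res_key & !double_called)
    tp <- sum(tp_mask)
    call_match <- ckey %in% tkey | (!is.na(hkey) & hkey %in% tkey) |
      ckey %in% paste(truth$contig, truth$npos, truth$nalt)
    fp <- sum(!call_match)
    geno_frac <- if (n_truth) sum(geno_ok) / n_truth else NA
  } else {
    # project truth onto haplotype A
    base <- sub("_[AB]$", "", truth$contig)
    ppos <- ifelse(truth$haplotype == "A", truth$npos,
                   homology_lookup_vec(genome$homology, base, truth$npos,
                                       truth$haplotype))
    unreachable <- sum(is.na(ppos))
    actg <- paste0(base, "_A")
    pkey <- ifelse(is.na(ppos), NA, paste(actg, ppos))
    ckey_pos <- paste(ret$contig, ret$pos)
    if (mode == "single_position") {
      tp_mask <- !is.na(pkey) & pkey %in% ckey_pos
      tp <- sum(tp_mask)
      fp <- sum(!(ckey_pos %in% pkey[!is.na(pkey)]))
      geno_frac <- NA_real_
    } else {
      # expected truth diploid genotype at the projected position
      geno_ok <- logical(n_truth)
      for (i in seq_len(n_truth)) {
        if (is.na(ppos[i])) next
        j <- which(ret$contig == actg[i] & ret$pos == ppos[i])
        if (!length(j)) next
        if (truth$kind[i] == "SNP") {
          gexp <- truth_diploid_genotype(genome, truth[i, ], ppos[i])
          geno_ok[i] <- any(ret$genotype[j] == gexp)
        } else {
          jj <- j[ret$ref[j] == truth$nref[i] & ret$alt[j] == truth$nalt[i]]
          geno_ok[i] <- length(jj) > 0 && any(ret$genotype[jj] == "REF/INDEL")
        }
      }
      tp_mask <- geno_ok
      tp <- sum(geno_ok)
      fp <- sum(!(ckey_pos %in% pkey[!is.na(pkey)]))
      geno_frac <- if (n_truth) tp / n_truth else NA
    }
  }
  fn <- n_truth - tp
  recall <- if (n_truth) tp / n_truth else NA
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA
  data.frame(mode = mode, coverage = coverage, tp = tp, fp = fp, fn = fn,
             unreachable = unreachable, recall = recall, precision = precision,
             f1 = f1, genotype_correct = geno_frac,
             haplotype_resolved = if (mode == "dual" && n_truth)
               hap_resolved / n_truth else NA_real_,
             stringsAsFactors = FALSE)
}

homology_lookup_vec <- function(hom, contigs, pos, from) {
  out <- rep(NA_integer_, length(pos))
  for (ct in unique(contigs)) {
    for (fr in unique(from)) {
      sel <- contigs == ct & from == fr
      if (any(sel)) out[sel] <- homology_lookup(hom, ct, pos[sel], from = fr)
    }
  }
  out
}

# expected diploid genotype string at a projected hapA position, given a
# truth SNP on one haplotype (handles tri-allelic germline-het collisions)
truth_diploid_genotype <- function(genome, trow, ppos) {
  base <- sub("_[AB]$", "", trow$contig)
  refA <- substring(genome$hapA[[paste0(base, "_A")]], ppos + 1, ppos + 1)
  germ <- genome$germline
  m <- germ[germ$contig == base & germ$kind == "SNP" & germ$posA == ppos, , drop = FALSE]
  aA <- refA
  aB <- if (nrow(m)) m$altB[1] else refA
  if (trow$haplotype == "A") aA <- trow$nalt else aB <- trow$nalt
  paste(sort(c(aA, aB)), collapse = "/")
}

#' Sweep calling performance across sequencing coverages
#'
#' Simulates reads from the mutated genome at each coverage, runs both the
#' dual-haplotype and the single-reference pipelines, and scores each against
#' the truth under the three evaluation assumptions.
#'
#' @param genome `diploid_genome`
#' @param truth `somatic_truth`
#' @param coverages fold-coverage grid (default 5 to 50 in steps of 5)
#' @param read_len,insert,error_rate read simulation parameters
#' @param blacklist_dual,blacklist_single blacklists per mode (built at the
#'   maximum coverage if not supplied; pass `NULL` explicitly to skip)
#' @param min_qual,min_depth caller filters
#' @param seed master seed
#' @param modes which mapping strategies to run
#' @return data frame of evaluation rows (one per mode x coverage)
#' @export
coverage_sweep <- function(genome, truth, coverages = seq(5, 50, by = 5),
                           read_len = 150, insert = c(400, 60),
                           error_rate = 0.002,
                           blacklist_dual, blacklist_single,
                           min_qual = 50, min_depth = 2, seed = 1,
                           modes = c("dual", "single")) {
  overlay <- apply_mutations(genome, truth)
  dual_ref <- c(genome$hapA, genome$hapB)
  if (missing(blacklist_dual) && "dual" %in% modes)
    blacklist_dual <- build_blacklist(genome, "dual", coverage = max(coverages),
                                      read_len = read_len, insert = insert,
                                      error_rate = error_rate,
                                      seed = child_seed(seed, "bl_dual"))
  if (missing(blacklist_single) && "single" %in% modes)
    blacklist_single <- build_blacklist(genome, "single", coverage = max(coverages),
                                        read_len = read_len, insert = insert,
                                        error_rate = error_rate,
                                        seed = child_seed(seed, "bl_single"))
  out <- list()
  for (cov in coverages) {
    reads <- simulate_reads(genome, cov, read_len, insert, error_rate,
                            seed = child_seed(seed, paste0("cov", cov)),
                            overlay = overlay)
    if ("dual" %in% modes) {
      aln <- map_reads(reads, dual_ref, mode = "dual", insert = insert)
      pl <- pileup(aln, dual_ref)
      calls <- call_somatic(pl, "dual", genome = genome,
                            blacklist = blacklist_dual, min_qual = min_qual,
                            min_depth = min_depth, error_rate = error_rate)
      out[[length(out) + 1L]] <- evaluate_calls(calls, truth, genome, "dual",
                                                coverage = cov)
    }
    if ("single" %in% modes) {
      aln <- map_reads(reads, genome$hapA, mode = "single", insert = insert)
      pl <- pileup(aln, genome$hapA)
      calls <- call_somatic(pl, "single", genome = genome,
                            blacklist = blacklist_single, min_qual = min_qual,
                            min_depth = min_depth, error_rate = error_rate)
      out[[length(out) + 1L]] <- evaluate_calls(calls, truth, genome,
                                                "single_position", coverage = cov)
      out[[length(out) + 1L]] <- evaluate_calls(calls, truth, genome,
                                                "single_genotype", coverage = cov)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plateau coverage of a recall curve
#'
#' The smallest coverage whose recall is within 1% (relative) of the recall
#' at the maximum coverage.
#'
#' @param sweep sweep table from [coverage_sweep()]
#' @param mode evaluation mode
#' @export
plateau_coverage <- function(sweep, mode) {
  s <- sweep[sweep$mode == mode, , drop = FALSE]
  s <- s[order(s$coverage), , drop = FALSE]
  rmax <- s$recall[nrow(s)]
  min(s$coverage[s$recall >= 0.99 * rmax])
}

#' Summarize a coverage sweep across mapping strategies
#'
#' Reports per-mode plateau coverage and plateau recall, genotype-correct
#' fractions, the ratio of dual-mode to single-mode detected somatic-map
#' sizes, and flags any violated expected orderings (position-level recall
#' must dominate genotype-level recall; dual-mode genotype correctness must
#' dominate single-mode).
#'
#' @param sweep sweep table from [coverage_sweep()]
#' @return list of class `strategy_summary`
#' @export
compare_strategies <- function(sweep) {
  modes <- unique(sweep$mode)
  need <- c("dual", "single_position", "single_genotype")
  if (!all(need %in% modes))
    warning("sweep is missing modes: ", paste(setdiff(need, modes), collapse = ", "))
  per_mode <- lapply(setNames(intersect(need, modes), intersect(need, modes)),
                     function(m) {
    s <- sweep[sweep$mode == m, , drop = FALSE]
    pc <- plateau_coverage(sweep, m)
    list(plateau_coverage = pc,
         plateau_recall = s$recall[s$coverage == pc][1],
         max_recall = max(s$recall),
         genotype_correct_at_plateau = s$genotype_correct[s$coverage == pc][1])
  })
  viol <- character(0)
  if (all(c("single_position", "single_genotype") %in% modes)) {
    sp <- sweep[sweep$mode == "single_position", ]
    sg <- sweep[sweep$mode == "single_genotype", ]
    m <- merge(sp, sg, by = "coverage", suffixes = c(".pos", ".gt"))
    if (any(m$recall.pos < m$recall.gt - 1e-9))
      viol <- c(viol, "single_position recall < single_genotype recall")
  }
  if (all(c("dual", "single_genotype") %in% modes)) {
    # the dual mode halves per-copy depth, so its curve rises later; genotype
    # dominance over single-reference calling is expected from the dual
    # plateau upward, not in the depth-starved low-coverage regime
    d <- sweep[sweep$mode == "dual", ]
    sg <- sweep[sweep$mode == "single_genotype", ]
    m <- merge(d, sg, by = "coverage", suffixes = c(".dual", ".sg"))
    m <- m[m$coverage >= plateau_coverage(sweep, "dual"), , drop = FALSE]
    if (any(m$genotype_correct.dual < m$genotype_correct.sg - 1e-9))
      viol <- c(viol, "dual genotype-correct < single genotype-correct at plateau")
  }
  ratio <- NA_real_
  if (all(c("dual", "single_position") %in% modes)) {
    pc <- per_mode$dual$plateau_coverage
    d_tp <- sweep$tp[sweep$mode == "dual" & sweep$coverage == pc][1]
    s_tp <- sweep$tp[sweep$mode == "single_position" & sweep$coverage == pc][1]
    ratio <- if (!is.na(s_tp) && s_tp > 0) d_tp / s_tp else NA_real_
  }
  structure(list(per_mode = per_mode, dual_vs_single_map_ratio = ratio,
                 ordering_violations = viol, sweep = sweep),
            class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat("strategy comparison\n")
  for (m in names(x$per_mode)) {
    pm <- x$per_mode[[m]]
    cat(sprintf("  %-16s plateau %g x, recall %.3f, genotype-correct %s\n", m,
                pm$plateau_coverage, pm$plateau_recall,
                ifelse(is.na(pm$genotype_correct_at_plateau), "-",
                       sprintf("%.3f", pm$genotype_correct_at_plateau))))
  }
  cat(sprintf("  dual/single detected-map ratio: %.2f\n", x$dual_vs_single_map_ratio))
  if (length(x$ordering_violations))
    cat("  ordering violations:", paste(x$ordering_violations, collapse = "; "), "\n")
  else cat("  orderings satisfied\n")
  invisible(x)
}
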