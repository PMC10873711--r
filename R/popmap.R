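#' Merge per-accession somatic calls into a population map
#'
#' Variants are keyed by (haplotype contig, position, ref, alt). The
#' genotype matrix distinguishes three states per accession: 0 = allele
#' confidently absent, 1/2 = present (het/hom), `NA` = no call (insufficient
#' evidence at that site) — a no-call is *not* treated as reference, which
#' matters for honest frequency spectra.
#'
#' @param call_sets named list (one element per accession) of
#'   `somatic_calls` data frames, or plain data frames with at least
#'   `contig`, `pos`, `ref`, `alt` (and optionally `genotype`)
#' @param nocall optional named list of data frames (`contig`, `pos`) of
#'   sites with insufficient depth per accession
#' @param clades optional named character vector of clade labels per accession
#' @return object of class `population_map`
#' @export
merge_population <- function(call_sets, nocall = NULL, clades = NULL) {
  stopifnot(length(call_sets) >= 1, !is.null(names(call_sets)))
  accs <- names(call_sets)
  vl <- lapply(accs, function(a) {
    x <- call_sets[[a]]
    if ("filter" %in% names(x)) x <- x[x$filter == "PASS", , drop = FALSE]
    x
  })
  allv <- do.call(rbind, lapply(vl, function(x)
    x[, c("contig", "pos", "ref", "alt"), drop = FALSE]))
  if (!nrow(allv)) stop("no retained calls to merge")
  # reference-build consistency: one ref allele per (contig, pos, nchar(ref))
  ksite <- paste(allv$contig, allv$pos, nchar(allv$ref))
  refs_by_site <- tapply(allv$ref, ksite, function(r) length(unique(r)))
  if (any(refs_by_site > 1))
    stop("conflicting reference alleles at the same position: ",
         "call sets are not against the same reference build")
  key <- paste(allv$contig, allv$pos, allv$ref, allv$alt, sep = ":")
  variants <- allv[!duplicated(key), , drop = FALSE]
  vkey <- key[!duplicated(key)]
  o <- order(variants$contig, variants$pos)
  variants <- variants[o, , drop = FALSE]
  vkey <- vkey[o]
  rownames(variants) <- NULL
  geno <- matrix(0L, nrow(variants), length(accs),
                 dimnames = list(vkey, accs))
  for (ai in seq_along(accs)) {
    x <- vl[[ai]]
    if (!nrow(x)) next
    k <- paste(x$contig, x$pos, x$ref, x$alt, sep = ":")
    dose <- if ("genotype" %in% names(x)) {
      gt <- x$genotype
      ifelse(!is.na(gt) & grepl("/", gt) &
               vapply(strsplit(gt, "/"), function(z) length(unique(z)) == 1, logical(1)) &
               !mapply(function(g, r) any(strsplit(g, "/")[[1]] == r), gt, x$ref),
             2L, 1L)
    } else rep(1L, nrow(x))
    geno[match(k, vkey), ai] <- dose
  }
  if (!is.null(nocall)) {
    site <- paste(variants$contig, variants$pos)
    for (a in names(nocall)) {
      if (!a %in% accs) next
      hit <- site %in% paste(nocall[[a]]$contig, nocall[[a]]$pos)
      geno[hit & geno[, a] == 0L, a] <- NA_integer_
    }
  }
  keep <- rowSums(!is.na(geno) & geno > 0) >= 1
  structure(list(geno = geno[keep, , drop = FALSE],
                 variants = variants[keep, , drop = FALSE],
                 accessions = accs,
                 clades = clades),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat("population_map:", nrow(x$geno), "variants x", ncol(x$geno),
      "accessions\n")
  invisible(x)
}

#' Remove windows whose variant load departs from the binomial expectation
#'
#' The genome is tiled with non-overlapping windows (50 kb by default); the
#' variant count of each window is tested against
#' Binomial(N_total, window_len / genome_len) with a two-sided exact test.
#' Windows with corrected p-values below `alpha` are removed together with
#' their variants.
#'
#' @param pm a [merge_population()] map
#' @param contig_lengths named lengths of all contigs in the map's
#'   coordinate system
#' @param window window size, bp
#' @param alpha significance level after correction
#' @param correction p-value adjustment method (see [stats::p.adjust()])
#' @return list with `map` (filtered `population_map`) and `windows`
#'   (per-window statistics, `removed` flag)
#' @export
binomial_window_filter <- function(pm, contig_lengths, window = 50000,
                                   alpha = 0.001, correction = "bonferroni") {
  G <- sum(as.numeric(contig_lengths))
  N <- nrow(pm$geno)
  rows <- list()
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    starts <- seq(0, max(0, L - 1), by = window)
    ends <- pmin(starts + window, L)
    v <- pm$variants[pm$variants$contig == ctg, , drop = FALSE]
    cnt <- if (nrow(v)) tabulate(findInterval(v$pos, starts), length(starts))
           else integer(length(starts))
    rows[[ctg]] <- data.frame(contig = ctg, start = starts, end = ends,
                              observed = cnt,
                              expected = N * (ends - starts) / G,
                              stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, rows)
  w$p_value <- vapply(seq_len(nrow(w)), function(i)
    binom.test(w$observed[i], N, (w$end[i] - w$start[i]) / G)$p.value,
    numeric(1))
  w$p_adj <- p.adjust(w$p_value, method = correction)
  w$removed <- w$p_adj < alpha
  rownames(w) <- NULL
  bad <- w[w$removed, , drop = FALSE]
  drop <- rep(FALSE, nrow(pm$variants))
  for (i in seq_len(nrow(bad))) {
    drop <- drop | (pm$variants$contig == bad$contig[i] &
                      pm$variants$pos >= bad$start[i] &
                      pm$variants$pos < bad$end[i])
  }
  out <- pm
  out$geno <- pm$geno[!drop, , drop = FALSE]
  out$variants <- pm$variants[!drop, , drop = FALSE]
  list(map = out, windows = w)
}

#' Polarize alleles with an outgroup and compute the frequency spectrum
#'
#' The ancestral allele at each variant is the allele fixed across all
#' genotyped outgroup accessions; variants polymorphic in the outgroup or
#' without outgroup genotypes are unresolved and excluded from the spectrum
#' (but counted). The spectrum tallies, for each occupancy k, the number of
#' variants whose derived allele occurs in exactly k ingroup accessions.
#'
#' @param pm a `population_map`
#' @param outgroup accession ids forming the outgroup
#' @return list of class `spectrum_result`: `spectrum` (named counts over
#'   occupancy 0..n_ingroup), `labels` (per-variant derived allele and
#'   occupancy), `unresolved`, `n_ingroup`, `low_freq_fraction` (occupancy
#'   < 3 among resolved variants)
#' @export
polarize_and_spectrum <- function(pm, outgroup) {
  if (!length(outgroup) || !all(outgroup %in% pm$accessions))
    stop("outgroup accessions absent from the population map")
  ing <- setdiff(pm$accessions, outgroup)
  og <- pm$geno[, outgroup, drop = FALSE]
  im <- pm$geno[, ing, drop = FALSE]
  n <- nrow(pm$geno)
  derived <- rep(NA_character_, n)
  occupancy <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    o <- og[i, ][!is.na(og[i, ])]
    if (!length(o) || length(unique(o > 0)) != 1) next # unresolved
    if (all(o == 0)) { # ancestral = ref, derived = alt
      derived[i] <- "alt"
      occupancy[i] <- sum(im[i, ] > 0, na.rm = TRUE)
    } else { # alt fixed in outgroup: ancestral = alt, derived = ref-state
      derived[i] <- "ref"
      occupancy[i] <- sum(im[i, ] == 0, na.rm = TRUE)
    }
  }
  resolved <- !is.na(occupancy)
  spec <- tabulate(occupancy[resolved] + 1L, nbins = length(ing) + 1L)
  names(spec) <- 0:length(ing)
  structure(list(
    spectrum = spec,
    labels = data.frame(pm$variants, derived = derived, occupancy = occupancy,
                        stringsAsFactors = FALSE),
    unresolved = sum(!resolved),
    n_ingroup = length(ing),
    low_freq_fraction = if (any(resolved))
      sum(occupancy[resolved] < 3 & occupancy[resolved] > 0) /
        sum(occupancy[resolved] > 0) else NA_real_),
    class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("derived-allele spectrum over", x$n_ingroup, "ingroup accessions;",
      x$unresolved, "unresolved\n")
  print(x$spectrum)
  invisible(x)
}

#' Screen for variants private to a group of accessions
#'
#' The strict screen keeps variants present (heterozygous or homozygous) in
#' every group member and confidently absent from every non-member; the
#' relaxed screen requires presence in at least one member. Variants are
#' annotated with genes whose body or +/- `proximity` bp flank they hit.
#'
#' @param pm a `population_map`
#' @param group accession ids (strict subset of the map's accessions)
#' @param annotation optional gene annotation ([synthesize_annotation()] or
#'   compatible) for proximity annotation
#' @param proximity flank width around gene bodies, bp
#' @param relaxed use the relaxed (>= 1 member) screen
#' @return data frame of screened variants with a `genes` column
#' @export
group_specific_screen <- function(pm, group, annotation = NULL,
                                  proximity = 3000, relaxed = FALSE) {
  stopifnot(length(group) >= 1, all(group %in% pm$accessions),
            length(group) < length(pm$accessions))
  g <- pm$geno[, group, drop = FALSE]
  o <- pm$geno[, setdiff(pm$accessions, group), drop = FALSE]
  in_group <- if (relaxed) rowSums(!is.na(g) & g > 0) >= 1
              else rowSums(!is.na(g) & g > 0) == length(group)
  absent_out <- rowSums(is.na(o) | o > 0) == 0
  keep <- in_group & absent_out
  res <- pm$variants[keep, , drop = FALSE]
  res$genes <- NA_character_
  if (!is.null(annotation) && nrow(res)) {
    gn <- annotation$genes
    base <- sub("_[AB]$", "", res$contig)
    for (i in seq_len(nrow(res))) {
      hit <- gn$gene_id[gn$contig == base[i] &
                          res$pos[i] >= gn$start - proximity &
                          res$pos[i] < gn$end + proximity]
      if (length(hit)) res$genes[i] <- paste(hit, collapse = ",")
    }
  }
  rownames(res) <- NULL
  res
}

#' Pairwise allele-sharing distances and NEXUS export
#'
#' Presence/absence Hamming distance: for each accession pair, the fraction
#' of variants (both genotyped) where exactly one of the two carries the
#' allele. Accessions with no genotyped site are dropped with a warning.
#'
#' @param pm a `population_map` with >= 3 accessions
#' @param file optional path for a NEXUS DISTANCES block (input for network
#'   phylogeny software)
#' @return symmetric distance matrix (invisibly returns the file path if
#'   `file` is given)
#' @export
export_distance_nexus <- function(pm, file = NULL) {
  if (ncol(pm$geno) < 3) stop("need >= 3 accessions for a distance matrix")
  pres <- pm$geno > 0
  ok_acc <- colSums(!is.na(pres)) > 0
  if (any(!ok_acc)) {
    warning("dropping accession(s) with no genotyped site: ",
            paste(colnames(pres)[!ok_acc], collapse = ", "))
    pres <- pres[, ok_acc, drop = FALSE]
  }
  n <- ncol(pres)
  d <- matrix(0, n, n, dimnames = list(colnames(pres), colnames(pres)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    both <- !is.na(pres[, i]) & !is.na(pres[, j])
    d[i, j] <- d[j, i] <- if (any(both))
      mean(pres[both, i] != pres[both, j]) else NA
  }
  if (!is.null(file)) {
    write_nexus_distances(d, file)
  }
  d
}
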