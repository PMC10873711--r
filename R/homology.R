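#' Construct a homology map between two haplotypes
#'
#' A homology map is a set of collinear blocks `(contig, a0, a1, b0, b1)`
#' (0-based half-open, equal lengths, forward strand) mapping haplotype A
#' coordinates onto haplotype B, plus gap regions private to one haplotype.
#' Within blocks the map is an involution: `lookup(lookup(x)) == x`.
#'
#' @param blocks data frame with `contig`, `a0`, `a1`, `b0`, `b1`
#' @param gaps optional data frame with `contig`, `side` ("A"/"B"), `start`,
#'   `end`, `other_pos`, `hap_specific`
#' @export
homology_map <- function(blocks, gaps = NULL) {
  stopifnot(all(c("contig", "a0", "a1", "b0", "b1") %in% names(blocks)))
  stopifnot(all(blocks$a1 - blocks$a0 == blocks$b1 - blocks$b0))
  blocks <- blocks[order(blocks$contig, blocks$a0), , drop = FALSE]
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, gaps = gaps), class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat("homology_map:", nrow(x$blocks), "block(s),",
      if (is.null(x$gaps)) 0 else nrow(x$gaps), "gap(s)\n")
  invisible(x)
}

#' Map positions between haplotypes through a homology map
#'
#' @param hom a [homology_map()]
#' @param contig base contig name (without the `_A`/`_B` suffix)
#' @param pos 0-based positions
#' @param from which haplotype the positions are on ("A" or "B")
#' @return integer vector of partner positions; `NA` where the position has
#'   no homolog (haplotype-specific or unaligned)
#' @export
homology_lookup <- function(hom, contig, pos, from = c("A", "B")) {
  from <- match.arg(from)
  bl <- hom$blocks[hom$blocks$contig == contig, , drop = FALSE]
  out <- rep(NA_integer_, length(pos))
  if (!nrow(bl)) return(out)
  if (from == "A") {
    bl <- bl[order(bl$a0), , drop = FALSE]
    i <- findInterval(pos, bl$a0)
    ok <- i > 0 & pos < bl$a1[pmax(i, 1)]
    out[ok] <- pos[ok] - bl$a0[i[ok]] + bl$b0[i[ok]]
  } else {
    bl <- bl[order(bl$b0), , drop = FALSE]
    i <- findInterval(pos, bl$b0)
    ok <- i > 0 & pos < bl$b1[pmax(i, 1)]
    out[ok] <- pos[ok] - bl$b0[i[ok]] + bl$a0[i[ok]]
  }
  out
}

# longest strictly increasing subsequence (patience sorting); returns indices
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  tails <- numeric(0)   # smallest tail value per length
  tails_i <- integer(0) # index of that tail
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tails) # first position with tail >= x[i]
    prev[i] <- if (j > 0) tails_i[j] else 0L
    tails[j + 1] <- x[i]
    tails_i[j + 1] <- i
  }
  out <- integer(length(tails))
  k <- tails_i[length(tails_i)]
  for (t in rev(seq_along(out))) { out[t] <- k; k <- prev[k] }
  out
}

#' Build a homology map between two haplotypes from shared unique k-mers
#'
#' Mutually unique shared k-mers are chained collinearly (longest increasing
#' chain per contig pair); runs of anchors with a constant offset become
#' blocks, and unchained spans of at least `min_gap` bp are reported as
#' haplotype-specific gaps. Assumes no rearrangement (collinear forward
#' chains only).
#'
#' @param hapA,hapB named character vectors of haplotype sequences; contigs
#'   are paired by base name (`chr1_A` with `chr1_B`)
#' @param k_anchor anchor k-mer size (odd, <= 63)
#' @param min_gap minimum unchained span reported as haplotype-specific
#' @param max_anchors subsample cap on anchors per contig (controls the
#'   boundary resolution near InDels)
#' @export
build_homology_map <- function(hapA, hapB, k_anchor = 31, min_gap = 50,
                               max_anchors = 50000) {
  stopifnot(k_anchor %% 2 == 1, k_anchor <= 63)
  blocks <- list(); gaps <- list()
  for (ca in names(hapA)) {
    base <- sub("_A$", "", ca)
    cb <- paste0(base, "_B")
    if (!cb %in% names(hapB)) next
    an <- cpp_homology_anchors(hapA[[ca]], hapB[[cb]], as.integer(k_anchor))
    if (!nrow(an)) {
      warning("no anchors found for contig ", base)
      next
    }
    if (nrow(an) > max_anchors) {
      an <- an[seq(1, nrow(an), length.out = max_anchors), , drop = FALSE]
    }
    keep <- lis_indices(an$posB)
    an <- an[keep, , drop = FALSE]
    off <- an$posB - an$posA
    # close a block when the offset changes
    brk <- which(diff(off) != 0)
    starts <- c(1L, brk + 1L); ends <- c(brk, nrow(an))
    bdf <- data.frame(contig = base,
                      a0 = an$posA[starts], a1 = an$posA[ends] + k_anchor,
                      b0 = an$posB[starts], b1 = an$posB[ends] + k_anchor)
    # trim overlap between adjacent blocks introduced by anchor spacing
    if (nrow(bdf) > 1) {
      for (i in 2:nrow(bdf)) {
        ov <- bdf$a1[i - 1] - bdf$a0[i]
        if (ov > 0) { bdf$a1[i - 1] <- bdf$a0[i]; bdf$b1[i - 1] <- bdf$b1[i - 1] - ov }
        ovb <- bdf$b1[i - 1] - bdf$b0[i]
        if (ovb > 0) {
          bdf$b1[i - 1] <- bdf$b0[i]
          bdf$a1[i - 1] <- bdf$a1[i - 1] - ovb
        }
      }
      bdf <- bdf[bdf$a1 > bdf$a0 & bdf$b1 > bdf$b0, , drop = FALSE]
    }
    # anchors only reach to the nearest clean shared k-mer, so blocks stop
    # short of the true event boundary. Stitch small inter-block regions:
    # align min(gapA, gapB) bases as a prefix before and a suffix after the
    # event, choosing the split that maximizes matching bases, and grow the
    # two flanking blocks accordingly. Large leftovers stay as gaps.
    sA <- hapA[[ca]]; sB <- hapB[[cb]]
    chA <- strsplit(sA, "")[[1]]; chB <- strsplit(sB, "")[[1]]
    nb <- nrow(bdf)
    # contig edges: extend first/last block outward while offsets permit
    if (nb >= 1) {
      g0 <- min(bdf$a0[1], bdf$b0[1])
      if (g0 > 0 && g0 < min_gap) { bdf$a0[1] <- bdf$a0[1] - g0; bdf$b0[1] <- bdf$b0[1] - g0 }
      g1 <- min(nchar(sA) - bdf$a1[nb], nchar(sB) - bdf$b1[nb])
      if (g1 > 0 && g1 < min_gap) { bdf$a1[nb] <- bdf$a1[nb] + g1; bdf$b1[nb] <- bdf$b1[nb] + g1 }
    }
    if (nb > 1) {
      for (i in seq_len(nb - 1)) {
        gA <- bdf$a0[i + 1] - bdf$a1[i]
        gB <- bdf$b0[i + 1] - bdf$b1[i]
        g <- min(gA, gB)
        if (g <= 0 || max(gA, gB) - g >= 200) next # large event: leave as gap
        av <- chA[(bdf$a1[i] + 1):(bdf$a1[i] + gA)]
        bv <- chB[(bdf$b1[i] + 1):(bdf$b1[i] + gB)]
        pref <- av[seq_len(g)] == bv[seq_len(g)]
        suff <- rev(rev(av)[seq_len(g)] == rev(bv)[seq_len(g)])
        # matches when the first s bases align before the event
        sc <- vapply(0:g, function(s)
          sum(pref[seq_len(s)]) + sum(suff[seq_len(g - s) + s]), numeric(1))
        s <- which.max(sc) - 1L
        bdf$a1[i] <- bdf$a1[i] + s; bdf$b1[i] <- bdf$b1[i] + s
        bdf$a0[i + 1] <- bdf$a0[i + 1] - (g - s)
        bdf$b0[i + 1] <- bdf$b0[i + 1] - (g - s)
      }
    }
    blocks[[base]] <- bdf
    # gap regions between consecutive blocks
    if (nrow(bdf) > 1) {
      for (i in 2:nrow(bdf)) {
        gA <- bdf$a0[i] - bdf$a1[i - 1]
        gB <- bdf$b0[i] - bdf$b1[i - 1]
        if (gA >= min_gap)
          gaps[[length(gaps) + 1L]] <- data.frame(
            contig = base, side = "A", start = bdf$a1[i - 1], end = bdf$a0[i],
            other_pos = bdf$b1[i - 1], hap_specific = gB < min_gap,
            stringsAsFactors = FALSE)
        if (gB >= min_gap)
          gaps[[length(gaps) + 1L]] <- data.frame(
            contig = base, side = "B", start = bdf$b1[i - 1], end = bdf$b0[i],
            other_pos = bdf$a1[i - 1], hap_specific = gA < min_gap,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(blocks)) {
    warning("homology map is empty")
    return(homology_map(data.frame(contig = character(), a0 = integer(),
                                   a1 = integer(), b0 = integer(),
                                   b1 = integer())))
  }
  homology_map(do.call(rbind, blocks),
               if (length(gaps)) do.call(rbind, gaps) else NULL)
}
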