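#' @useDynLib hapsoma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom rpois rnorm runif binom.test p.adjust
#'   pbinom quantile sd dbinom setNames
#' @importFrom utils write.table read.table head
#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One master seed drives every stochastic stage; each stage re-seeds from a
#' stable hash of `(seed, stage)` so that stages can be re-run independently
#' without disturbing each other's random streams.
#'
#' @param seed master integer seed
#' @param stage character stage label
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute bases at 0-based positions `pos` of `seq` with `alt` (single chars)
substitute_bases <- function(seq, pos, alt) {
  r <- charToRaw(seq)
  r[pos + 1L] <- charToRaw(paste(alt, collapse = ""))
  rawToChar(r)
}

phred <- function(p_err) {
  q <- -10 * log10(pmax(p_err, 1e-30))
  pmin(q, 300)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Left-normalize a variant against its reference sequence
#'
#' Shifts an indel to its leftmost equivalent representation and trims shared
#' trailing/leading bases, following the usual VCF normalization convention.
#' Positions are 0-based.
#'
#' @param seq reference contig sequence
#' @param pos 0-based position of the first base of `ref`
#' @param ref,alt allele strings
#' @return list with `pos`, `ref`, `alt`
#' @export
normalize_variant <- function(seq, pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    # trim identical trailing base
    if (nr > 1 && na > 1 && substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1, nr - 1); alt <- substr(alt, 1, na - 1)
      next
    }
    # left-shift: last bases equal and room to prepend
    if (nr != na && pos > 0 && substr(ref, nr, nr) == substr(alt, na, na)) {
      prev <- substr(seq, pos, pos) # 0-based pos => preceding base is at `pos` 1-based
      ref <- paste0(prev, substr(ref, 1, nr - 1))
      alt <- paste0(prev, substr(alt, 1, na - 1))
      pos <- pos - 1
      next
    }
    break
  }
  # trim identical leading bases while both keep >= 1
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}
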