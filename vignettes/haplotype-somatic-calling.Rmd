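---
title: "Haplotype-resolved somatic mutation detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved somatic mutation detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hapsoma)
```

## The problem

Clonally propagated crops (citrus, grapevine, potato, many fruit trees)
accumulate somatic mutations over centuries of grafting. Almost all of these
mutations are heterozygous: they arise on one chromosome copy and are never
resolved by meiosis. In a highly heterozygous diploid — sweet orange, an
interspecific pummelo x mandarin hybrid, carries roughly 18 heterozygous SNPs
per kb in its aligned regions plus tens of thousands of large
haplotype-specific segments — a single "collapsed" reference genome makes
somatic mutation detection hard in two ways:

1. Reads from both chromosome copies pile onto one coordinate system, so a
   somatic mutation (allele fraction ~50%) is statistically indistinguishable
   from the dense germline heterozygous background without knowing that
   background exactly, and the *genotype* of the call is easily wrong.
2. Sequence private to the non-reference haplotype simply has nowhere to map;
   mutations there are invisible.

The haplotype-based ("dual-reference") strategy maps reads against both
assembled haplotypes concatenated into a single reference. Germline
heterozygosity then disappears — every read lands on the copy it came from,
and each haplotype contig behaves like a haploid sequence — while a somatic
heterozygous mutation surfaces as a near-fixed allele on one haplotype contig.
`hapsoma` implements this strategy end-to-end on synthetic data with complete
ground truth, together with the population-level analyses built on top of it
(clonal network distances, outgroup-polarized frequency spectra, a
Jukes-Cantor-corrected and neutrality-normalized dN/dS, and allele-specific
expression classification).

## The synthetic diploid genome

`generate_diploid()` builds haplotype A as uniform random sequence and derives
haplotype B by applying sampled germline variation; the exact homology map is
recorded while doing so and is the ground truth against which the anchor-based
map (`build_homology_map()`) and all evaluations are checked.

The sweet-orange-like preset (`so_genome_config()`) fixes the study
conditions:

* `snp_rate = 0.018` per bp of aligned sequence — the published heterozygous
  SNP density of the system this emulates;
* `indel_rate = 0.0018` per bp — reported somatic maps in this system carry
  roughly one short InDel per ten SNPs, and the same ratio is a reasonable
  choice for the germline background, for which no single published density
  exists;
* 10 haplotype-specific segments per Mb with exponentially distributed
  lengths (mean 5 kb, floor 50 bp — the conventional SV size floor), half
  private to each haplotype, totalling ~5% of a haplotype. The real genome's
  haplotype-specific fraction is not printed as a single number; a few
  percent with occasional large segments reproduces the qualitative behavior
  (single-reference blindness, homology-map gaps) at desk scale;
* germline InDel lengths geometric (p = 0.35, capped at 50 bp), below the SV
  floor by construction.

What the generator deliberately does **not** emulate: transposable elements
and tandem repeats (no repeat-family simulation), CNVs and inversions,
GC-content and sequencing-platform error structure. The consequences are
discussed under *Limitations*.

Somatic mutations (`spike_somatic()`) are placed uniformly over both
haplotypes, heterozygous by construction, with alt bases drawn from a
configurable base-substitution matrix (the equal-rate `jc_matrix()` by
default) and 10% short InDels (geometric length, p = 0.5, capped at 20 bp —
a concrete reading of "short"). Position collisions are resolved by
resampling, never by overwriting. With a clone tree (`clone_tree()`),
mutations attach to branches and accumulate from the root down, so any leaf
carries exactly its root-path mutations — the oracle for all
population-level tests.

Read simulation (`simulate_reads()`) interprets total coverage against the
length of one haplotype and splits it evenly between the two copies, matching
how diploid WGS coverage is normally quoted. Reads are 150 bp paired-end,
insert 400 +/- 60 bp, with a uniform 0.2% substitution error rate injected
independently of the constant Q30 quality string; these are configurable
defaults of this package, chosen as typical short-read values, not claims
about any particular sequencing campaign.

## Mapper, pileup, homology

The mapper is a minimal seed-and-extend aligner: canonical k-mer seeds
(k = 21) vote for candidate diagonals, candidates are verified by unit-cost
banded alignment, and the placement with the minimum edit distance wins.
Representation details that matter downstream:

* exact ties (regions identical between haplotypes) are kept in
  `alts`, broken lexicographically by (contig, position), and flagged MAPQ 0;
  an ambiguous mate is rescued through proper-pair consistency (MAPQ 20);
  a unique best placement gets MAPQ 60 when it beats the runner-up by >= 2
  edits, 30 at a 1-edit margin;
* the alignment traceback prefers continuing a gap on cost ties, so one InDel
  is never split into two cost-equal adjacent gaps (which would shatter the
  pileup's InDel alleles);
* ungapped placements with at most 5 mismatches are accepted without dynamic
  programming; a gapped alignment could only beat them for an InDel within a
  few bp of a read end, and InDel-bearing reads otherwise produce large
  Hamming distances and fall through to the DP.

The homology map chains mutually-unique shared k-mers (k = 31) with a longest
increasing subsequence, merges constant-offset runs into blocks, and stitches
the short inter-anchor interstices around InDels by choosing the split point
that maximizes matching bases. Unchained spans of >= 50 bp are reported as
haplotype-specific gaps. The map assumes collinearity; inversions are out of
scope. On generator output the built map agrees with the truth map at
> 99.9% of SNP positions.

## The caller

`genotype_site()` is a maximum-likelihood genotyper under binomial sampling
with a per-base error prior and a flat prior over genotypes.

**Dual mode** treats each haplotype contig as one chromosome copy. The
hypothesis set per column is: a pure allele per observed allele; a 50:50
*mixed* state of reference and alt — this models cross-mapping in regions
where the haplotypes are locally identical, where the pileup deliberately
counts MAPQ-0 reads and the lexicographic tie-break stacks both copies'
reads on one coordinate; and a low-fraction (10%) *noise* state per alt that
absorbs the residue of locally misaligned reads and is treated as
non-variant. Without the mixed state, mutations in identical regions would
be unclassifiable; without the noise state they would be over-called. The
noise states carry a small prior weight (0.01) rather than a flat prior:
misaligned-residue columns are rare and clustered near structural
differences, while the mixed state is the expected signature of a real
mutation wherever the copies are indistinguishable — a flat noise prior
would cap the variant quality of genuine mixed columns at moderate depth
below the calling threshold.

**Single mode** genotypes diploid allele pairs (including tri-allelic pairs)
and declares a site somatic when the called genotype differs from the
reference individual's expected genotype — heterozygous at its germline
variants, homozygous-reference elsewhere. The germline variant set of the
reference individual is therefore an input to single-mode calling, exactly as
a real single-reference pipeline must first catalogue the reference
accession's own heterozygosity.

**Quality.** `QUAL` is the Phred-scaled posterior of the no-variant
hypothesis (in single mode, of the *expected* genotype) — the confidence that
the site is somatic, which is what the default `quality >= 50` filter acts
on. The genotype-resolution confidence is reported separately as `GQ`. Tying
the filter to variant existence rather than genotype resolution keeps the
dual mode's genotype-correctness dominance over single mode intact: a
genotype-posterior filter would paradoxically punish the dual mode in exactly
the balanced-mix columns it is designed to rescue. The `depth >= 2` filter is
applied per pileup column, i.e. per haplotype in dual mode (a flagged,
configurable choice).

**Blacklist.** `build_blacklist()` simulates mutation-free reads from the
unmutated genome, calls variants with a permissive quality floor (20), and
blacklists every called position: these are systematic artifacts of the
reference structure, not of any particular read set. In single mode the
neighbourhood (+/- 10 bp) of every germline heterozygous InDel is added
deterministically: reads spanning such an InDel are placed ambiguously around
it and leak shifted alleles, and read sampling decides which representation
surfaces in any one run, so a single stochastic null simulation cannot
enumerate them all. Blacklist matching pads by +/- 2 bp for the same reason.

**Deduplication.** In dual mode, `dedup_homologous()` compares the 150 bp
flanks around each call with the flanks around its homologous position
(truncated symmetrically at contig ends). If both flank pairs are exactly
identical the two coordinates are indistinguishable to short reads and calls
at the two homologous positions merge into one; the haplotype-A coordinate is
kept (which copy survives is a free choice; a fixed lexicographic rule
makes the operation deterministic and idempotent) and the partner is flagged
`DUP` with a cross-reference. Calls inside homology gaps are untouched —
there is no homologous coordinate to compare.

## Evaluation

`evaluate_calls()` scores call sets under the three mapping assumptions:
dual (haplotype-resolved position + allele; merged/ambiguous calls match
through their partner coordinate), single-position (haplotype-B truth
projected through the homology map, position-only), and single-genotype
(the called diploid genotype must equal the truth genotype, including
tri-allelic sites). Unprojectable truth positions (homology gaps) are
reported as `unreachable` and count as missed. Dual-mode *genotype-correct*
means the call implies the correct heterozygous genotype: a merged or
copy-ambiguous call still does; only a failed dedup — both homologous
positions retained separately, implying homozygosity — does not. The stricter
haplotype-resolved fraction is reported alongside. InDels are matched after
VCF-style left-normalization on both sides.

`coverage_sweep()` runs the full pipeline over a 5-50x grid and
`compare_strategies()` summarizes plateau coverage/recall and flags violated
orderings (position-level recall must dominate genotype-level recall;
dual-mode genotype correctness must dominate single-mode).

At the package's reference scale (two 1-Mb haplotypes, 600 spiked mutations,
35x), dual-mode recall and precision are both close to 1, the single-mode
position recall is a few points lower (haplotype-specific regions and
germline-InDel neighbourhoods are invisible or masked), and the single-mode
genotype-correct fraction is lower still. These levels are substantially
higher, and the coverage plateau substantially earlier, than the original
study reports on the real genome, for reasons the simulator makes explicit:
about 45% of the real genome is repetitive, so a large fraction of real
mutations fall where short reads cannot be placed uniquely regardless of
strategy, and a CNN-based caller demands considerably more depth for a
confident call than an exact binomial model does on data whose errors really
are independent and uniform, as simulated here. The *orderings* between the
strategies and the flattening of the recall curve by 35x are the
reproduction targets that transfer to desk scale; the absolute percentages
are not. Passing tests therefore demonstrate the mechanism — the het
background vanishes under dual mapping, genotypes come out right, duplicate
homologous calls collapse — not field performance on a repeat-rich genome.

## Population, selection and expression layers

* `merge_population()` keys variants by (haplotype contig, position, ref,
  alt) and distinguishes "confidently absent" (0) from "no call" (`NA`) —
  conflating the two would bias every spectrum downstream.
* `binomial_window_filter()` tests each non-overlapping 50-kb window's
  variant count against Binomial(N, window/genome), two-sided exact, with
  Bonferroni correction at alpha = 0.001 by default. Exact two-sided with
  Bonferroni is the conservative default; both the sidedness and the
  correction are arguments.
* `polarize_and_spectrum()` takes the ancestral allele to be the one fixed
  across all genotyped outgroup accessions; variants polymorphic or uncalled
  in the outgroup are counted as unresolved rather than guessed.
* `group_specific_screen()` implements the strict reading (present in every
  group member, confidently absent everywhere else) with a relaxed (>= 1
  member) variant, plus gene-body/+/- 3 kb proximity annotation.
* `export_distance_nexus()` writes presence/absence Hamming distances
  (pairwise-complete, dosage-ignored — natural for a clonal presence matrix)
  as a NEXUS DISTANCES block for network phylogeny software.
* `estimate_mutation_matrix()` tallies substitutions on the reference strand
  as printed (no pyrimidine collapsing, which would discard strand
  information the simulator actually has).
* dN/dS: site-counting, not codon-model ML — `dnds_raw()` converts observed
  N and S counts into proportions of the annotation's N/S opportunity,
  Jukes-Cantor corrects each (d = -(3/4) ln(1 - (4/3) p)), and takes the
  ratio; a pseudo-count of 0.5 synonymous observations guards against
  division by zero and is flagged. `simulate_neutral()` (R = 100 replicates
  by default) draws mutation sets under the empirical matrix, and
  `normalized_dnds()` divides the observed ratio by the neutral mean. The
  uncertainty band is reported both as the replicate standard deviation and
  as an order-statistic 95% band, since a bare "mean +/- spread" report is
  ambiguous between the two.
* ASE: reads vote per covered heterozygous coding SNP and are assigned by
  majority (ties discarded and counted); the allelic balance test is
  two-sided exact binomial against 0.5 with Benjamini-Hochberg FDR within
  stage (replicates pooled by default; a per-replicate mode and a global
  FDR switch are exposed). EASE requires,
  strictly, fold change > 2, high-allele count > 100 and FDR < 0.001; fold
  change uses raw counts with no pseudo-count, so a zero low-allele count
  gives fold infinity and qualifies through the other thresholds.
  `promoter_sv_association()` flags genes with a heterozygous SV in the
  strand-aware 3-kb window upstream of the TSS.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based in VCF/SAM output.
* Genotype likelihoods are computed in log space with log-sum-exp; Phred
  values are capped at 300.
* A substitution-matrix row with no observations falls back to the uniform
  1/3 row with a warning; `jc_distance()` refuses p >= 0.75 (saturation).
* Mapper tie-breaks, dedup survivor choice and clone-tree branch order are
  all deterministic, so identical seeds give identical output bytes.
* One master seed; each pipeline stage derives a child seed by stable
  hashing of (seed, stage name), so stages can be re-run independently.
* Problem sizes used by the test-suite: the simulation-study reproduction
  runs two 1-Mb haplotypes at 35x with 600 spiked mutations, and the
  coverage sweep runs two ~300-kb haplotypes over the 5-50x grid; both are
  the package's reference desk-scale configurations.

## Known limitations

* No repeats, no CNV/inversion grammar, no platform error profiles: absolute
  recall/precision on real repeat-rich genomes will be lower than on
  generator output (see *Evaluation*).
* The mapper has no soft-clipping: reads straddling a haplotype-specific
  segment boundary go unmapped rather than partially mapped.
* Single-mode somatic InDel detection masks germline-InDel neighbourhoods
  and so cannot detect a somatic event that destroys a germline InDel.
* The homology map is collinear-only; a rearranged genome needs an external
  whole-genome aligner.
* SV calling from short reads is out of scope, as are deleteriousness
  scores; the SV inputs to the ASE association are taken from the germline
  truth or an external VCF/BED.
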