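---
title: "Methods: phasing two heterozygous variants on a cDNA amplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasing two heterozygous variants on a cDNA amplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliphase)
```

## The model

A patient heterozygous for two variants in one gene has one of two
haplotype configurations.  Writing R/A for the reference/alternate
allele at sites 1 and 2, the two parental mRNA haplotypes are either

* **trans**: (A, R) and (R, A) — a compound heterozygote, or
* **cis**: (A, A) and (R, R).

A sequenced read pair that observes both sites draws one of these
haplotypes, so with p the probability that a pair is assigned to the
correct haplotype class, the counts of the four configurations
(n_RR, n_RA, n_AR, n_AA) among double-informative pairs follow a
multinomial concentrated on the diagonal (cis) or the off-diagonal
(trans).  `call_phase()` uses the majority class directly: with
cis support n_RR + n_AA and trans support n_RA + n_AR, a configuration
is called when its support fraction reaches `min_support_fraction`
(default 0.9) over at least `min_informative` (default 10) pairs.  The
reported p-value is the two-sided exact binomial probability of the
observed minority count under a symmetric Binomial(n, 0.5) null — a
conservative guard against template chimerism and residual error.  It
is reported for transparency but does not drive the call, because under
either true configuration the minority count is far below any
0.5-null quantile long before the support threshold is met.

Differential allelic expression is estimated per site as the alt
fraction of deduplicated molecule counts, n_A / (n_R + n_A), with an
exact binomial test against a null fraction (default 0.5, i.e.
balanced biallelic expression) using the minimum-likelihood two-sided
definition, and a Clopper–Pearson 95% interval.  A markedly reduced
fraction for an allele carrying a premature termination codon is
*consistent with* nonsense-mediated decay; the package reports the
imbalance and its direction, never NMD as a computed fact.
`haplotype_expression()` gives the same quantity at the haplotype
level: the two phase-consistent classes' fractions, plus the
phase-inconsistent fraction as a QC metric.

### Assumptions

* Exactly two non-overlapping variants (SNV or simple indel) on one
  amplicon; complex variants are rejected.
* Reads come from the targeted amplicon only (no off-target
  contamination model).
* Context k-mers occur uniquely within the amplicon (checked
  implicitly: a read matching both contexts of a site is AMBIGUOUS and
  excluded, and such pairs are reported as conflicts).

## Allele calling by exact context matching

Each variant is represented by a `ContextPair`: the reference window
around the edited region and the same window with the edit applied.
Calls are exact substring matches of these contexts in the read
(`match_allele()`), searching both strands for orientation-unknown
FASTQ input.  Exact matching (0 mismatches) is deliberate: the
distinguishing feature of an insertion inside a homopolymer run is the
run length itself (6 G's vs 7 G's), and any mismatch tolerance would
collapse that distinction.  The price is sensitivity — a sequencing
error anywhere in the context makes the read uninformative at that
site — which the uninformative/conflict accounting makes visible
rather than hiding.

### The flank rule

`build_contexts(ref_window, offset, variant, flank = 4)` constructs
the pair as follows:

1. The *anchor region* is the edited bases; for an insertion or
   deletion of base b adjacent to a run of b's, the anchor extends over
   the entire run (a read must see the whole run plus a non-run base on
   each side before run length is evidence of anything).
2. `flank` bases are taken on each side of the anchor.  If the window
   cannot supply a full flank on either side, the whole window is used:
   a short window is taken as the analyst's deliberate choice of
   context.  This is why a 10-base window around an SNV yields the full
   10-mer pair rather than a 9-mer centred slice.
3. If the two contexts are not mutually distinguishable (one a
   substring of the other), flanks grow symmetrically one base at a
   time; exhausting the window is an error, as is a homopolymer run
   touching the window edge (no anchor base available).

The default flank of 4 yields the conventional ~10-base site-specific
sequences for an SNV.  Flank is configurable; larger flanks buy
specificity at the cost of error sensitivity (longer context = higher
chance of containing an error).

## Mate merging and tabulation

Each mate is called independently at each site and merged with
`merge_mate_calls()`: NONE defers, agreement stands, REF-vs-ALT is a
contradiction (AMBIGUOUS), AMBIGUOUS dominates.  A contradictory or
repetitive-match call invalidates only that site, but any AMBIGUOUS
site marks the pair as a conflict in the table, excluded from phasing
and reported.  `tabulate_pairs()` classifies every pair into exactly
one of: the four double-informative cells, single-site informative (A
or B), uninformative, or conflict — counts are conserved by
construction and property-tested.

## UMI deduplication

Duplicates are collapsed *before* any counting, so that (possibly
allele-biased) PCR amplification cannot distort allele fractions.  Two
methods:

* **exact** — one representative per identical (UMI, anchor);
* **directional** — the published UMI-tools default: within an anchor,
  a directed edge a→b exists when Hamming(a, b) ≤ 1 and
  count(a) ≥ 2·count(b) − 1; components reachable from the
  highest-count node collapse to one molecule.  Neighbours are found by
  hashing all single-base substitutions, so clustering is
  O(UMIs × 3 × length).

The grouping anchor is the alignment start interval for alignment
input; in alignment-free amplicon mode every fragment shares the same
start, so the pair's two-site call signature is used instead.

Two deliberate refinements, both needed to make deduplication
idempotent (dedup(dedup(X)) = dedup(X), which we consider a basic
sanity property of a collapsing operator and verify by property test):
the representative of a cluster is drawn from the pairs carrying the
cluster's *root* (highest-count) UMI — among those, highest mean base
quality, ties by smallest name — and it carries the root UMI's
collapsed count forward in a `dup_count` column that weights any
subsequent pass.  Without the carried counts, all counts reset to 1
after a first pass and the 2n−1 rule (1 ≥ 2·1−1) merges every
surviving Hamming-1 pair on a second pass.

### When *not* to use directional collapse

Directional clustering exists to absorb UMI *sequencing errors*.  It
assumes UMI-space occupancy is sparse: each true molecule surrounded
by low-count error satellites.  On a single-anchor amplicon with N
molecules and 4^8 = 65,536 possible 8-mers, the expected number of
*distinct-molecule* Hamming-1 neighbour pairs grows like
N²·24/(2·4^8) — about 800 at N = 2,000 and 18,000 at N = 10,000 — and
singleton neighbours always satisfy the 2n−1 rule.  The larger allele
class loses proportionally more molecules, biasing allele fractions
toward 0.5; we measured a bias of ≈ +0.04 on a simulated 0.30 fraction
at 3,000–10,000 molecules.  The simulator attaches UMIs without
errors, so in that world directional collapse has nothing to correct
and only over-merges.  Consequently the expression-recovery analyses
(and the acceptance script) use `dedup_method = "exact"`, which is
unbiased up to true UMI collisions (birthday effect, ≈ +0.006 at
10,000 molecules); `directional` remains the pipeline default for
phase calling, where merging happens within a signature class and
cannot flip the configuration.  With real data and UMI errors,
directional is appropriate at moderate depth, or use longer UMIs.

## The simulator's stated world

`sim_config()` defaults describe the targeted cDNA scenario the
package is built around:

| parameter | default | rationale |
|---|---|---|
| amplicon length | 621 bp | targeted RT-PCR product size |
| read length | 2 × 250 bp | MiSeq paired-end chemistry |
| site A | SNV C>T at position 80 | embedded `CCCGTGGACC` window |
| site B | G dup in 6-G run at position 543 | embedded `ATGGGGGGCG` window |
| site span | 464 bp inclusive | the mRNA distance the method exploits |
| `hap1_fraction` | 0.5 | balanced heterozygote |
| `library_mode` | amplicon | direct adapter ligation |
| `fragment_len_mean/sd` | 350 / 80 bp | typical tagmentation insert |
| `sub_error_rate` | 0.001 | Illumina-like substitution rate |
| `umi_len` | 8 | common single-UMI kit length |
| `pcr_duplication_mean` | 2 | amplicon libraries are duplicate-rich |

In amplicon mode the fragment is the whole molecule, so the mates read
inward from the two amplicon ends and (at 250 bp) jointly cover both
sites — every error-free pair is double-informative.  In fragmentation
mode fragment length ~ Normal(350, 80) truncated to [50, molecule],
with uniform start: most fragments cover at most one site, reproducing
qualitatively why direct adapter ligation detects both-site read pairs
and tagmentation essentially does not.  `pcr_duplication_mean` may be
a length-2 vector for per-haplotype (allele-biased) amplification,
used to demonstrate that UMI collapse restores unbiased allele
fractions.

What the simulator does **not** model — and hence what a green test
does not establish: indel sequencing errors (an indel error inside a
context behaves like a substitution there: the read goes
uninformative, a case already accounted; but homopolymer-specific
indel error *rates* are not represented), quality-score variation
(qualities are constant Phred 37; only dedup representative choice
reads them), UMI sequencing errors, splicing/intron retention,
transposase insertion bias, chimeric PCR templates, and
alignment/mapping artefacts.  Phase-recovery rates measured here are
therefore upper bounds for real libraries with error modes outside
this list.

## Numerical choices

* Genomic distance is the plain coordinate difference; the kb figure is
  rounded half-up to one decimal (base R's `round()` is half-even).
  The cDNA span is the *inclusive* count |c2 − c1| + 1: both
  conventions are stated in the report, and the inclusive one is what
  makes a span of coordinates 1841 and 2304 equal 464.
* Coordinates are 1-based closed (HGVS/VCF); BED12 is converted at the
  reader boundary.  Indel `gpos` is the first affected base with the
  shared anchor-base convention.
* The exact binomial machinery is `stats::binom.test` (minimum-
  likelihood two-sided p, Clopper–Pearson interval); tests verify it
  against a from-scratch pmf-enumeration oracle to 1e-12 at all depths
  ≤ 200.
* Ties: `call_phase` prefers CIS when cis and trans support are exactly
  equal, which can only be reported as AMBIGUOUS anyway at any
  `min_support_fraction` > 0.5; dedup ties are broken by quality then
  lexicographic name, making every pipeline output deterministic.
* Degenerate inputs: zero-depth sites carry no test; an empty table
  yields INSUFFICIENT_DATA; a homopolymer run touching the window edge
  is an error rather than a silent ambiguous context.

## Limitations

* Two variants only; no multi-variant haplotype assembly, and no
  statistical phasing across reads that each see one site.
* Exact matching cannot rescue reads with an error in the context;
  coverage demands scale with context length.
* The cis/trans decision assumes a diploid mixture of two haplotypes;
  somatic mosaicism or >2 haplotypes would surface as AMBIGUOUS or a
  low support fraction.
* Alignment input is used only as a read-pair container (no CIGAR);
  soft-clipped bases are part of the stored sequence and are searched.
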