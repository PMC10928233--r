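---
title: "Quantifying mismatch repair deficiency: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mismatch repair deficiency: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrdkit)
```

## The problem

Loss of DNA mismatch repair (MMRD) leaves two durable marks on a genome:
hypermutation, and microsatellite instability (MSI) — length changes at
short tandem repeats caused by uncorrected polymerase slippage. Clinically
these are read out at several scales: a genome-wide "MMRDness" score from
low-pass whole-genome sequencing, the classical five-locus Promega panel on
capillary electrophoresis, tumor mutation burden (TMB) from exome variant
calling, and the relative activity of MMRD-associated mutational signatures
(COSMIC signature 6 / SBS6 being the hallmark). `mmrdkit` implements all
four read-outs as one tested pipeline, with a simulator that generates
every input with known ground truth. The interesting biological setting is
*tissue-specific* MMRD — e.g. epithelial-restricted MSH2 silencing — where
different tissues from the same patient sit at different points of the
deficiency gradient, and concordance of the read-outs across tissues is the
scientific claim of interest.

## The MMRDness (genome-wide MSI) score

The score operates on mononucleotide microsatellites — maximal homopolymer
runs in the reference — of 10 to 15 bp, inclusive. From aligned reads:

1. A read *observes* a locus when its alignment spans the full run plus at
   least one flanking base on each side.
2. A spanning read is a *slippage read* when its alignment contains exactly
   one deletion event intersecting the run, of exactly 1 base, fully inside
   the run. Insertions and deletions of 2+ bp do not count: the statistic is
   defined on 1-bp deletions, the dominant MMRD slippage product at
   mononucleotide runs.
3. A locus is *deleted* when at least `min_support` (default 1) slippage
   reads observe it. At ~1x coverage most observed loci have exactly one
   read, so the default is the only workable operating point; deeper data
   can raise it.
4. Per run length $L \in \{10,\dots,15\}$, the deleted fraction is
   $f_L = n^{del}_L / n_L$ over *observed* loci. Unobserved loci are
   uninformative at 1x and are excluded from the denominator (an option the
   catalog interface leaves open to change, since the full reference
   catalog is available).
5. The score is
   $$s = \log_{10}\left(\tfrac{1}{|\mathcal L|}\sum_{L} f_L\right) + 1.1,$$
   with $s > 0$ called MMRD and $s \le 0$ MMR-proficient (the boundary is
   assigned to proficient: the offset exists precisely to put the decision
   threshold at zero).

**Logarithm base.** The base is not dictated by the score's definition
beyond "a logarithmic transformation"; we default to base 10 because the
+1.1 offset then places the threshold at a mean deleted fraction of
$10^{-1.1} \approx 7.9\%$ of observed loci — a plausible operating point
between proficient (<1–3%) and deficient (>15%) regimes — whereas a natural
log would imply an implausible 33%. The base is a parameter
(`log_base`), recorded in the result's provenance.

**Degenerate inputs.** Empty length bins are excluded from the mean and
listed in provenance; an all-empty table is an error. A sample with zero
deletions at pseudocount 0 yields `raw_score = -Inf` with the proficient
call and a provenance flag; a small `pseudocount` keeps scores finite when
that matters (default 0, so the statistic is exactly the defined ratio).

## Panel MSI

The five mononucleotide loci (BAT-25, BAT-26, NR-21, NR-24, MONO-27) are
read from fragment-analysis peak tables. The *representative allele* of a
locus is the highest peak flanked on both sides by strictly lower peaks —
the stutter-flanked main allele. A boundary peak cannot satisfy the
flanking rule; when no interior peak does (single-peak or monotone
profiles) we fall back to the global maximum, making the function total on
degenerate electropherograms. Height ties break toward the shorter allele,
the direction MSI deletions move; both the tie-break and the rule are
invariant to uniform rescaling of heights.

A locus is unstable at a shift of $\ge 3$ bp between test and normal
representative alleles ($\le 2$ bp is stable); shifts count in either
direction since instability is defined by displacement, not sign. The
sample is MSI-High with $\ge 2$ unstable loci, MSI-Low with exactly 1, and
MS-Stable with 0. Loci missing from either profile shrink the assayed
denominator and flag the result as an incomplete panel; MSI-High still
requires two unstable loci among those assayed. Heterozygous-like profiles
with two genuine alleles are not modelled separately: one representative
allele is chosen by the same rule.

## Consensus TMB

Per-caller VCFs are atomized (one alt per record), left-normalized
(shared suffix then prefix trimmed, position advanced), de-duplicated
within caller, and matched on the full (contig, position, ref, alt)
identity — position-only matching would conflate distinct substitutions.
Variants supported by $\ge$ `min_callers` (default 2) callers form the
consensus, partitioned into SNVs and indels. TMB is consensus SNVs per
callable megabase; the callable size defaults to a scalar 50 Mb (a
whole-exome callable footprint) rather than being computed from coverage,
which is out of scope. A combined SNV+indel rate is reported for reference
but never drives the hypermutator call, which is strictly `tmb > 10`
mut/Mb — a sample at exactly 10 is not a hypermutator. Mixed `chr1`/`1`
contig naming across callers is an error rather than a silent zero-overlap
merge.

## Signature refitting

Consensus SNVs are channelized into the 96 trinucleotide channels
(pyrimidine-normalized reference; purine-reference variants are
reverse-complemented together with their context), in lexicographic COSMIC
order — the order is written into every output to prevent silent
misalignment. Refitting solves the non-negative least squares problem
$$\hat e = \arg\min_{e \ge 0} \lVert c - S e \rVert_2$$
for catalog $c$ and column-stochastic signature matrix $S$, reporting
exposures, percentage contributions, the reconstruction, its cosine
similarity to the catalog, and the residual norm. Plain NNLS refitting is
used, not sparsity-inducing "strict" variants; rank-deficient matrices are
solved but flagged. The MMRD-signature read-out sums the contributions of a
configurable id set, defaulting to the MMRD-associated ids present in the
matrix (`Signature.6` for COSMIC V2-style matrices; `SBS6`, `SBS15`,
`SBS21`, `SBS26`, `SBS44` for V3-style).

Reference matrices are user-supplied TSVs in the COSMIC download format.
The package ships `synthetic_signatures()` (and the same matrix as
`inst/extdata/signatures_synthetic_96x4.tsv`): a deterministic 96x4
matrix whose columns qualitatively mimic SBS1 (CpG C>T), SBS5 (flat),
SBS6 (non-CpG C>T plus T>C) and SBS15 (C>A-weighted). It is synthetic —
useful because its columns are well-separated, so recovery failures
indicate implementation error rather than collinearity — and it is not a
substitute for real COSMIC values when analysing real catalogs.

## What the simulator emulates — and what it does not

The generator produces each pipeline input with machine-readable truth:

* **Reference**: one contig with the configured number of maximal
  homopolymers per length (default 10 each of 10–15 bp), separated by
  spacers of at least 5 bp in which adjacent bases always differ, so the
  embedded loci are exactly the homopolymers of length $\ge 2$. Placement
  failure (genome too short) is an explicit error naming the constraint.
* **Reads**: `Poisson(coverage)` reads per locus (default coverage 1, the
  low-pass design point), spanning the run with 5–15 bp flanks; each read
  independently carries a 1-bp run deletion with probability
  `slippage_del_rate`, encoded in its CIGAR. There is no sequencer error
  model, no base qualities, no realignment: reads are born aligned, because
  the scoring logic under test is post-alignment.
* **Caller sets**: `n_variants` true variants (10% 1-bp indels by
  default), each emitted by each of `caller_count` callers independently
  with probability `caller_overlap`; caller-private false positives default
  to 0 (caller noise is not characterized here) but are configurable.
* **Catalogs**: multinomial draws of `n_mutations` channel assignments
  from the mixture-weighted channel distribution.
* **Panel profiles**: per locus a main peak at a realistic amplicon size
  with stutter peaks at ±1 bp (50% of main height) and ±2 bp (25%) —
  values chosen so the flanked-peak rule is genuinely exercised — with
  ±10% height jitter that preserves the strict main > stutter ordering;
  the test profile's main peak moves `panel_shifts[locus]` bp toward
  shorter alleles.

Consequently, passing tests demonstrate that the *rules and estimators* are
implemented correctly and recover known truth under the stated stochastic
models; they do not demonstrate robustness to alignment artifacts, PCR
stutter in sequencing reads, impure tumors, diploid genotypes, or caller
error profiles, none of which are modelled. In simulation mode the
pipeline's signature stage draws its catalog directly from the configured
mixture rather than channelizing the simulated VCFs: the homopolymer-rich
synthetic genome cannot realize arbitrary trinucleotide context
distributions. The VCF+FASTA channelization route (`build_catalog()`) is
exercised on its own fixtures.

Every simulator is a pure function of its config and seed (each uses the
seed plus a fixed offset so stages draw independent streams), restores the
caller's RNG state, and returns ground truth separately from the data files
— no test parses truth back out of an artifact.

## Orchestration and determinism

`run_pipeline()` validates its config against the known threshold set
before any compute, runs the stages in dependency order, writes per-stage
artifacts and a machine-readable `status.json` as it goes (a failing stage
leaves completed artifacts in place and names itself in the error), and
returns a `sample_report` whose provenance — seed, thresholds, simulation
parameters, package version — is sufficient to re-run bit-identically.
Reports contain no timestamps for exactly that reason. `compare_samples()`
sorts reports by TMB (ties broken by sample id, so the table is invariant
to input order) and flags whether the MMRDness and MMRD-signature orderings
agree — the testable form of the normal → polyp → cancer gradient claim.

## Problem sizes in the tests

The statistical tests use sizes chosen so sampling noise is far from the
decision boundaries while the suite stays quick: 10,000 loci for read-level
calibration (binomial 3-standard-error bands), 500 loci per length bin for
the slippage-separation runs (the expected deficient/proficient gap there
is ~20 standard errors), 1,000 truth variants for consensus calibration,
and catalogs of 10,000 mutations for signature recovery (20 seeds, ±3
percentage points). The end-to-end gradient uses three samples spanning
slippage 0.02→0.30, 80→1830 truth variants, and SBS6 weight 0.1→0.8 —
deliberately wide spacing, since the claim under test is ordering, not
effect size.

## Known limitations

* Mononucleotide repeats only; di-/tri-nucleotide and compound repeats are
  out of scope (the panel loci are mononucleotide and the score is defined
  on 1-bp deletions).
* No mappability or uniqueness masking of the locus catalog; a mask hook
  exists in the sense that any subset of the catalog can be supplied.
* Whole files are read into memory; the package targets desk-scale and
  simulated data, not production BAMs. Sorted/indexed input is therefore
  not required.
* TMB's callable size is a scalar parameter, not derived from coverage.
* De novo signature extraction (NMF), indel/doublet signatures, and strict
  refitting variants are out of scope.
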