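---
title: "Methods: trio variant prioritization, larval motility, and qPCR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio variant prioritization, larval motility, and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triofish)
```

`triofish` implements three analyses that together take a family-trio exome
to a candidate disease gene and then quantify the functional consequences of
knocking that gene down in zebrafish larvae: (1) inheritance-model variant
prioritization, (2) larval motility analysis, and (3) relative qPCR
quantification. Each analysis has a seeded generator producing synthetic
input with known ground truth, so every stage is testable end to end without
any external data.

## 1. Trio variant prioritization

### The funnel

An annotated trio exome (proband, mother, father) enters a fixed sequence of
stages, with counts recorded at each:

1. **Functional-class filter** — keep nonsynonymous coding variants, coding
   indels shorter than 50 bp, and splice-site variants; these are the
   classes most likely to perturb the gene product.
2. **Rarity filter** — keep variants with catalogued minor allele frequency
   (MAF) strictly below 1%, or with no catalogue entry at all. The boundary
   case (exactly 1%) is removed: we define "rare" as strictly less than the
   cutoff.
3. **Inheritance models** — test each surviving variant (or pair) against
   four trio-genotype predicates:
   * *de novo* (dominant): proband het — or hemizygous-alt on chrX/chrY in
     a male — with both parents reference;
   * *homozygous recessive*: autosomal, proband hom-alt, both parents het;
   * *compound heterozygous*: two distinct proband-het variants in one
     gene, one transmitted from each parent (trans configuration; the
     transmitting parent may be het or hom-alt). A permissive mode that
     pairs any two hets in a gene is available for sensitivity analysis but
     is off by default, because cis pairs leave one intact gene copy;
   * *X-linked hemizygous*: chrX in a male proband, proband hemizygous-alt,
     mother het, father reference.
4. **Database exclusion** — dominant candidates are removed if present in
   *any* population database (dbSNP, 1000 Genomes, EVS, ExAC): a dominant
   pathogenic allele should not be segregating. Recessive candidates are
   removed only if databases contain *homozygotes* (carriers are expected
   for recessive alleles); X-hemizygous candidates only if databases
   contain hemizygotes. A compound-het pair is excluded if either member
   has homozygote evidence.

Records with any missing trio genotype are untestable; they are skipped and
counted rather than silently dropped. Genotype configurations that are not a
possible meiotic outcome of the parents (e.g. a hom-alt proband with a
reference parent) are tallied as `inconsistent` — they most plausibly
reflect genotyping error — and never called; the de novo pattern itself is
by definition non-meiotic and is *not* counted there, since it is exactly
the dominant model's signature.

A male proband's de novo hemizygous variant on chrX (both parents
reference) is reported under the de novo model, not the X-hemizygous model:
the dominant model is defined by de novo status, not by chromosome.

### Evidence tally and ranking

Surviving candidates are scored by a transparent count rather than a
weighted composite: five prediction tools (CADD ≥ 20, PolyPhen2 ≥ 0.85,
PROVEAN ≤ −2.5, SIFT ≤ 0.05, MutationTaster ≥ 0.5 ⇒ damaging) and three
conservation scores (PhyloP ≥ 2, PhastCons ≥ 0.9, GERP ≥ 2 ⇒ conserved).
Missing scores contribute neither way. Candidates are ordered by tally, then
CADD, then gene symbol; compound-het pairs rank by their better member. All
cutoffs are defaults from common tool conventions and are overridable via
`prioritization_thresholds()` — the tally is meant to be read, not trusted
blindly. Final adjudication between top candidates typically rests on
clinical phenotype match, which is not computable here and deliberately not
encoded.

`codon_of_cds_position()` maps a coding-nucleotide position to its residue
index (`floor((pos − 1)/3) + 1`), which is how a missense such as c.875C>T
is placed at codon 292 and checked against annotated protein domains (for
the GABA~A~ receptor α1 subunit, residues 279–300 form the TM2
transmembrane helix).

### The trio generator

`simulate_trio()` emulates a called, annotated trio exome — not reads or
raw calling. Background variants get a MAF from a two-component mixture
(common: Uniform(0.05, 0.5); rare: Uniform(0.0001, 0.009); the rare
fraction defaults to 0.2, roughly the rare-to-functional proportion seen in
real exome funnels). Parental genotypes are drawn at Hardy–Weinberg
proportions and the proband receives one transmitted allele per parent, so
every background genotype is Mendelian-consistent; on chrX the father is
hemizygous and a son draws from the mother only. Database fields derive
from the MAF: presence flags are true for any catalogued variant, and
homozygote counts are Binomial with Hardy–Weinberg expectation at database
scale (6,500 exomes for EVS, 60,000 for ExAC).

Separability of planted and background variants at
`genotype_error_rate = 0` is guaranteed by construction: de novo patterns
cannot arise by transmission, and any background record whose genotypes
happen to match a recessive or X pattern has its database
homozygote/hemizygote count floored at one, so the exclusion stage always
removes it. Planted variants occupy dedicated genes outside the background
pool (so a background het can never join a planted compound-het pair), are
nonsynonymous, uncatalogued, and carry damaging score vectors. What passing
recovery tests therefore shows is that the *logic* of the funnel is exact —
not that real exomes separate this cleanly: real data add genotyping error,
incomplete annotation, and population structure that this generator does
not emulate (read depth is likewise not simulated).

## 2. Larval motility

### Metrics

The tracker reports, per animal and per integration bin (300 s), distance
and duration of small and large movements (`smldist`, `lardist`, `smldur`,
`lardur`; mm and s). Per animal:

* total distance = Σ(smldist + lardist) over bins;
* swim speed = Σ(smldist + lardist) / Σ(smldur + lardur).

Swim speed is a **ratio of sums**, not a mean of per-bin speeds — the two
differ whenever movement time varies across bins, and the ratio-of-sums is
the quantity defined by the swim-speed formula (it is the time-weighted
mean of bin speeds, so it always lies between the per-bin extremes). An
animal that never moves has distance 0 and an undefined speed; it is kept
for distance analyses and excluded, with a logged count, from speed
statistics (a deliberate, visible choice — conventions differ between labs).

The default protocol is 15 min of dark/light/dark, 5 min each, matching the
integration period; phase windows are half-open `[start, end)` and a bin
straddling a boundary is treated as a malformed export (error, not a
guess).

### Statistics

Group contrasts use a two-tailed two-sample *t*-test, Student's
(pooled-variance) by default to match the field's "standard two-tailed
t-test", with Welch as an option. Two analysis levels are supported:
per-animal (each larva one observation — the *n* shown in figure panels)
and per-replicate (replicate means as observations — what "SEM of
independent experiments" error bars describe). Neither is silently chosen;
the level is recorded in every result row. Zero-variance degenerate inputs
are flagged rather than producing `NaN`. No multiple-testing correction is
applied across contrasts by default, matching common practice for these
panel-style comparisons; `p.adjust` can be applied downstream where wanted.

The PTZ (pentylenetetrazol) response is the treated/untreated fold change
in speed and distance with the same test machinery. PTZ is a GABA~A~
receptor antagonist; wild-type larvae roughly double swim speed and
increase distance about six-fold under treatment, which is why those are
the generator's default treatment effects in the demo.

### The tracking generator

`simulate_tracks()` draws per-bin distance as
`baseline × group multipliers × phase multiplier × noise`, with mean-one
lognormal noise at coefficient of variation `noise_cv` (distances are
positive and right-skewed; 0.2 is typical between-larva variability).
Defaults: 300 mm distance and 60 s movement per dark 300-s bin (≈ 5 mm/s,
a realistic 5-dpf larval cruise speed), light-phase activity at 0.6 of
dark (larvae settle under bright light), 12 animals per group in 3
replicates. A hypoactivity factor (default 0.5) scales distance in
designated groups with movement time unchanged, so speed scales equally —
the morphant phenotype. PTZ treatment scales distance by
`ptz_distance_factor` and movement duration by
`ptz_distance_factor / ptz_speed_factor`, so both planted fold changes are
realized simultaneously; durations are clamped to the bin length (with the
default baselines the clamp binds with probability < 1%, a negligible
bias). The generator does not emulate video artifacts, tracking dropouts,
habituation drift, or startle transients at phase changes.

## 3. qPCR quantification

Technical replicates (triplicates by convention) are collapsed to a mean Ct
per (sample, gene); a replicate SD above 0.5 cycles is flagged for
inspection, not dropped — automatic dropping hides pipetting problems.
Relative expression uses the Livak method: ΔCt per sample (gene Ct minus
reference-gene Ct, or the raw gene Ct in input-normalized mode when
normalization was by RNA mass upstream — the default here, since no
reference gene is assumed), ΔΔCt = mean ΔCt(treated) − mean ΔCt(control),
fold change = 2^−ΔΔCt. Higher expression ⇒ lower Ct ⇒ fold change > 1.
The *t*-test runs on per-sample ΔCt values, not on fold changes, because Ct
noise is approximately additive on the log2 scale; testing ratios directly
would be right-skewed at these small *n*.

`simulate_qpcr()` plants log2 fold changes per gene:
Ct = baseline − log2FC × 1(treated) + N(0, `ct_sd`²) per biological
sample, plus N(0, `tech_sd`²) per technical replicate. Defaults (baseline
Ct 25, biological SD 0.15, technical SD 0.05 cycles, triplicates, three
biological samples per group) reflect a clean SYBR assay. The default demo
panel is the GABA~A~ receptor subunit family with β2 and γ2 transcripts
planted at log2FC −1 and α6b at +1 — the qualitative directions seen when
the α1 subunit is knocked down (magnitudes are not published numbers; ±1 is
a representative, comfortably detectable effect). Amplification-efficiency
correction (Pfaffl) and melt-curve QC are out of scope.

## Numerical and design notes

* **Determinism.** Every generator takes an explicit integer seed and seeds
  R's RNG once at entry; identical seeds give byte-identical output files.
  Writers stamp the package version, a 32-bit FNV-1a configuration
  fingerprint, and the seed into header comments; no timestamps are
  written anywhere.
* **Genotype dialects.** Male chrX/chrY calls are written single-allele
  (`0`/`1`); the reader also accepts `1/1` as hemizygous-alt for males,
  since both dialects occur in real callers. Phased separators (`|`) are
  accepted, phase ignored. Any missing allele makes the genotype
  `missing`. Chromosome labels are normalized by stripping a leading
  `chr`.
* **Multiallelic sites** are split into one record per ALT allele, each
  genotype decoded against its own allele index.
* **Annotation transport** is a sidecar TSV keyed on (chrom, pos, ref,
  alt), mirroring external annotation tools and keeping the VCF
  caller-agnostic; key collisions are fatal, unmatched rows are counted and
  warned about, never silently dropped.
* **Problem sizes.** The test suite exercises recovery at 5,000 background
  variants across 20 seeds, oracle equivalence on 500 random trios of up to
  200 variants, and behavior/qPCR recovery at 50 animals and 10 biological
  samples per group — sizes at which the stochastic recovery targets have
  comfortable margins while the full suite runs in well under a minute.
* **Limitations.** The funnel reproduces rule-based prioritization only;
  it does not re-annotate consequences, recalculate population frequencies,
  or model genotype quality. The behavioral statistics assume approximate
  normality of per-animal metrics at moderate *n*; heavy-tailed outliers
  (dead or stuck larvae) should be excluded upstream. The qPCR module
  assumes perfect amplification efficiency.
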