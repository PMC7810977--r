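---
title: "Phasing hemiclonal inheritance in water-frog crosses"
author: "hemiphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing hemiclonal inheritance in water-frog crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiphase)
library(dplyr)
```

## The biological problem

Hybridogenesis is hemiclonal reproduction: a hybrid transmits one parental
genome to its gametes clonally, without recombination, and replaces the other
each generation by mating with a sexual host species. In Central-European
water frogs, hybrid *Pelophylax esculentus* males (RL; one *P. ridibundus* R
genome and one *P. lessonae* L genome) live among *P. ridibundus* (RR) and
fertilise RR females. A male transmitting clonal [L] sperm makes new RL
hybrids; a male transmitting clonal [R] sperm makes RR daughters; a single
male doing both is *amphispermic*. Under the XX–XY model with the
male-determining factor on the [L] genome, [L]-sperm offspring are sons and
[R]-sperm offspring daughters.

Testing these claims from an experimental cross requires, per offspring,
splitting the diploid genotype into the gamete received from the mother
(recombinant, sexual) and the gamete received from the father (putatively
clonal). That is the core of this package: pedigree-based haplotype phasing
for *non-Mendelian* inheritance, plus the downstream analytics that make
clonality, amphispermy, genome leakage and linkage statements quantitative.
A seeded cross simulator with complete ground truth makes every stage
testable without any external dataset.

## Data model

Three tabular inputs drive everything (all tibble-first, CSV/TSV on disk):

* **Locus registry** (`locus_registry()`, `read_locus_registry()`): for each
  marker, the alleles diagnostic for the L genome and for the R genome.
  Microsatellite alleles are fragment lengths in bp, SNP alleles base
  symbols; both are opaque tokens, so one phasing engine serves both marker
  types. Diagnostic sets must be disjoint per locus. Registry row order is
  the canonical locus order for all outputs.
* **Genotype table** (`genotype_table()`, `read_genotypes()`,
  `read_snp_vcf()`): one row per (individual, locus) with the unordered
  allele pair. Missing data is explicit; a half-call (one observed allele)
  keeps its single allele but is treated as missing for phasing and present
  for multilocus-genotype comparison — phasing from half-information would
  invite silent errors, while discarding the observed allele would waste
  clonality evidence.
* **Pedigree** (`read_pedigree()`): cross id, mother, father, offspring and
  recorded sex. Sex is phenotypic metadata only; no genetic call ever uses
  it, so the sex-concordance column of `summarize_families()` remains an
  independent check of the XX–XY model.

## Taxon assignment

`assign_taxa()` scores, per individual, the number of loci carrying
L-specific and R-specific alleles. Both at `min_support` or more loci gives
RL; only one side (with the other side at zero loci) gives RR or LL; anything
weaker stays `unknown`. The default `min_support = 2` exists because a single
leaked allele is a documented phenomenon: one diagnostic locus must not be
able to flip a classification. Shared (non-diagnostic) alleles never count as
evidence. `assess_ploidy()` uses allele counts only (more than two alleles at
a locus flags a possible polyploid); peak-intensity dosage evidence is
outside the data model.

```{r}
reg <- waterfrog_loci()
count_diagnostic_alleles(reg)
```

## The phasing engine

`phase_family()` runs per family (one cross), in four stages.

**1. Locus filtering** (`filter_family_loci()`): a locus is retained when
both parents have non-missing calls and at least `offspring_presence` of the
offspring do (default 0.75, the filter used for phased datasets in this
design; the stricter 0.95 used at raw SNP-calling stages is available as a
parameter, and `phase_families(presence_scope = "union")` retains loci
passing in at least one family). In SNP mode a within-family site with more
than two alleles is dropped as `multiallelic`.

**2. Null-allele screening** (`screen_null_alleles()`): a null allele in one
parent makes null/allele progeny look homozygous. The screen flags any locus
where an offspring is apparently homozygous for an allele that one parent
does not show while the other does, and the locus is removed from phasing.
Only fully typed parents are screened — a half-called parent cannot prove
absence.

**3. Per-offspring, per-locus enumeration**: the offspring's allele pair
{a, b} admits at most two assignments to (maternal, paternal). An assignment
is Mendelian-consistent if the maternal allele occurs in the mother and the
paternal in the father. Then the gamete class constrains the paternal side:
for an [L] gamete the paternal allele must be L-specific, or non-diagnostic
but *father-exclusive* (present in father and offspring, absent from the
mother); symmetrically for [R]. The per-locus status is

* `phased` — exactly one assignment survives;
* `ambiguous` — several survive (e.g. both parents share a genotype);
* `conflict` — none survives. Conflicts are recorded, never fatal: a unique
  Mendelian assignment whose paternal allele is diagnostic for the *wrong*
  genome is precisely the signature of genome leakage and must reach the
  leakage detector, not abort the family;
* `missing` — offspring or a parent not fully typed at the locus.

The offspring's gamete class inside a hybrid family is decided from
L-diagnostic support measured against the father's own L-diagnostic content
(an [L] gamete shows L alleles at about all of the father's L-diagnostic
loci, an [R] gamete at rare leaked ones; the boundary sits at half). This is
deliberately more robust than the strict taxon call: an [R]-gamete offspring
with one or two leaked L alleles must be phased as [R] with locus-level
conflicts, not dismissed as unclassifiable.

**4. Clonal consensus**: within one gamete class, the paternal haplotype must
be identical across offspring. The father's [L] (and [R]) haplotype is the
per-locus mode of the phased paternal alleles (a tie yields no consensus at
that locus); each side is additionally completed as the complement of the
other side within the father's own genotype. Ambiguous loci are then
re-resolved against the consensus, and phased loci that deviate from it are
flipped to `conflict` ("paternal haplotype inconsistency"). Control RR × RR
families are phased with plain Mendelian trio logic — no clonal constraint,
shared parental genotypes stay ambiguous.

The engine never imputes: with non-Mendelian inheritance, a Mendelian prior
on missing data is exactly the assumption under test.

`phase_offspring()` exposes stage 3 alone; every status it emits is verified
in the test suite against an independent brute-force oracle that enumerates
all mother-allele × father-allele transmissions.

## Downstream analytics

* **MLG clustering** (`mlg_key()`, `cluster_mlgs()`): a haplotype's raw
  multilocus genotype is its allele string in registry order, `~` for
  missing. Haplotypes with more than `max_missing` (default 0.65) missing
  loci are excluded; the rest are sorted (most complete first, then by id —
  the fixed order makes the result order-invariant) and greedily merged into
  clusters of mutually compatible haplotypes (equal wherever both defined),
  with representatives filling in from members. Compatibility is not
  transitive, so a haplotype compatible with several clusters joins the
  first and carries an `ambiguous` flag rather than an invented
  probabilistic assignment. Raw key counts per cluster stay visible: the
  distinction between raw MLG diversity and missing-data-merged clusters is
  scientifically meaningful and both are reported.
* **Gamete profiles** (`classify_gamete_profiles()`): an RL offspring of a
  hybrid father evidences [L] sperm, an RR offspring [R] sperm; evidence is
  pooled over all the father's crosses; both classes together mean
  amphispermy. Offspring sex is never used.
* **Leakage detection** (`detect_leakage()`): emits one event per
  (offspring, locus) where the paternal haplotype carries a cross-genome
  diagnostic allele, or a consensus-deviant allele equal to the father's
  other-genome allele. Unattributable conflicts (allele in neither parent —
  mutation, genotyping error, contamination) are left in the conflict table
  with their description; the package does not guess among explanations.
* **Two-point linkage** (`two_point_rf()`): among one parent's transmitted
  haploid gametes, each locus pair's recombination fraction is the minority
  phase-pairing count over jointly typed gametes, taking the pairing that
  minimises recombinants, so r̂ ∈ [0, 0.5]. Clonal transmission gives r̂ = 0
  everywhere ("complete linkage"); independent loci in a recombining mother
  give r̂ near 0.5. Only loci heterozygous in the parent are informative
  when the parent genotype is supplied. This deliberately replaces full map
  construction: the scientific claim is linkage-vs-recombination, not map
  order, and standard mapping software assumes Mendelian segregation.
* **Summaries** (`summarize_families()`): per-cross progeny counts by taxon
  × sex, totals, and the sex-concordance column.

`run_pipeline()` wires all stages into seven TSV reports plus a JSON
manifest of parameters and versions; identical inputs reproduce every file
byte for byte (the manifest deliberately contains no timestamp).

## The simulator

`simulate_system()` generates a full crossing experiment with ground truth
(`sim_truth`): hybrid fathers carrying one hemiclonal [L] haplotype (shared
within a hemiclone) and one clonal [R] haplotype; sexual RR mothers whose
gametes recombine along a configurable female map; per-father gamete
profiles drawn from configurable probabilities; offspring sex tied to the
paternal gamete class (a simulated Y marker, transmitted to half the control
male's sperm, covers the RR × RR control). `study_like_config()` pins the
generic machinery to the study design this package targets: 16 hybrid
fathers × 2–3 of nine shared mothers plus an RR control male crossed with
all females; the published 15-locus registry as diagnostic allele pools;
clutch sizes resampled from the observed 17 per-cross totals; profile
probabilities 9:1:2 for [L]-only : [R]-only : amphispermic, the observed
pattern among 12 fathers.

Choices a user should know:

* **Allele frequencies** are uniform within each pool — published diagnostic
  tables list alleles, not frequencies. Non-diagnostic (shared) pools are
  generated deterministically per locus (`default_shared_pools()`), since
  real genotypes contain alleles the two species share.
* **Leakage** is modelled as a per-locus substitution of the father's
  other-genome allele inside an otherwise clonal gamete — the smallest model
  consistent with a single-allele observation; whole-arm recombination would
  be a different (and here unsupported) claim. Leaks are injected at loci
  where that other-genome allele is species-diagnostic: where the two
  genomes share allele states, a substitution is either a no-op or
  indistinguishable from a maternal transmission, so "a leak" is not a
  well-defined event there. This also makes detection exactly scoreable
  against truth.
* **Null alleles** are designated per (parent, locus, haplotype copy); the
  parent types as an apparent homozygote and every offspring inheriting the
  null copy shows only the other parent's allele (duplicated, as a fragment
  analysis would read it). Truth records which masking events carry the
  detectable signature.
* **Missingness** is applied last, independently per call.
* **Determinism**: one seed drives everything; per-cross substreams are
  derived by a stable hash of the cross id, so a family's contents do not
  depend on the order in which crosses are generated.

What the simulator does **not** emulate: genotyping error (mistyped
alleles), allele dropout correlated with fragment length, triploids,
population structure among mothers, multi-generation dynamics, or
linkage between the microsatellite loci (real ones were chosen to be
independent). Passing tests on simulated data therefore demonstrate
correctness of the inference logic under the stated model, not robustness
to every real-data artifact; the locus filters and the conflict/ambiguous
statuses are the designed escape hatches for real data.

## Verification sizes and numerical conventions

The shipped tests and the acceptance script run, per stage: the published
fixture tables (15 loci, 17 crosses, exact equality); 500–1,000 random
small trio families (≤ 10 loci, ≤ 6 offspring) against the enumeration
oracle; a clean study-sized simulation (~700 offspring) for exact recovery
of profiles, haplotypes and the single hemiclone; ~1,400–2,000 meioses at
leak rate 0.01 for leakage precision/recall; 40 clonal and 500 maternal
gametes for the linkage contrast (binomial 3-SE band around 0.5); and
byte-level hash comparison for determinism. These sizes give the binomial
checks comfortable power while keeping the whole suite in a few minutes on
one core.

Conventions: alleles sort numerically when both tokens are numbers (so
`"124"` < `"1300"`), lexically otherwise; the MLG missing token `~` sorts
after alphanumerics; consensus ties yield no consensus rather than an
arbitrary winner; iteration is always in (cross id, registry locus,
offspring id) order, making every output reproducible.

## Known limitations

* Phasing power comes from diagnostic alleles and father-exclusive alleles;
  families whose parents share genotypes at a locus stay ambiguous there.
  This is reported, not hidden.
* The leakage detector requires the leaked allele to be attributable to the
  father (diagnostic contradiction or consensus deviation to his other
  genome). A leak indistinguishable from a maternal allele is undetectable
  in principle with unlinked markers.
* `two_point_rf()` assumes gametes of a single diploid parent; pooled
  gametes from several parents violate the two-allele assumption and yield
  `NA`.
* The greedy MLG clustering is deterministic but order-dependent in the
  constructed tie cases it flags as `ambiguous`; it is a missing-data
  merge rule, not a mixture model.
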