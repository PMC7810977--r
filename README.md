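# hemiphase

Pedigree-based phasing and clonality analysis for hybridogenetic
(hemiclonal) crosses, built for the water-frog system in which hybrid
*Pelophylax esculentus* males (RL) mate with sexual *P. ridibundus* females
(RR) and transmit a parental genome **clonally** — [L] sperm producing
hybrid sons, [R] sperm producing *P. ridibundus* daughters, and single
amphispermic males producing both.

## Who it is for

Population geneticists analysing experimental crosses (microsatellites or
biallelic SNPs) in any hemiclonal system where offspring genotypes must be
split into a recombinant maternal haplotype and a putatively clonal paternal
haplotype, and where clonality, amphispermy, genome leakage and linkage need
to be quantified per family.

## The method in brief

For offspring *o* with unordered genotype {a, b} in family (mother *M*,
father *F*), the engine enumerates the assignments (maternal, paternal) with
maternal ∈ *M* and paternal ∈ *F*, then constrains the paternal allele by
gamete class: for an [L] gamete it must be L-specific or *father-exclusive*
(present only in father and offspring, not the mother); symmetrically for
[R]. A unique survivor is `phased`, several are `ambiguous`, none is a
recorded `conflict` — and a conflict whose paternal allele is diagnostic for
the *other* genome is the signature of genome leakage. Within a gamete
class the paternal haplotype must be constant across offspring, so the
father's [L]/[R] haplotypes are per-locus consensuses, ambiguous loci are
re-resolved against them, and deviants become conflicts. Loci pass a
presence filter (both parents + ≥ 75 % of offspring typed) and a null-allele
screen first. Downstream: multilocus-genotype clustering with a 65 %
missing-data cap, per-father gamete-profile classification, leakage events,
and two-point recombination fractions r̂ = min(phase pairings)/n ∈ [0, 0.5]
contrasting clonal (r̂ = 0) against recombining (r̂ ≈ 0.5) transmission.

A seeded simulator (`simulate_system()`, `study_like_config()`) generates
the whole crossing design with ground truth, so every stage is testable
offline. Details and design rationale: `vignettes/hemiclonal-phasing.Rmd`.

## Worked example

The packaged synthetic single-leak family (a father, a mother and eight RL
sons, one of which inherited the father's R-specific allele at Re1Caga10
instead of his clonal [L] allele):

```r
library(hemiphase)
reg <- waterfrog_loci()
g   <- read_genotypes(hemiphase_example("family60_genotypes_synthetic.csv"), reg)
ped <- read_pedigree(hemiphase_example("family60_pedigree_synthetic.csv"))

pf <- phase_family("60-2013", ped, g, reg)
pf
#> <phased_family> cross 60-2013 (hybrid): M13 x F60
#>   15 retained loci, 8 offspring phased, 1 conflicts

detect_leakage(pf, reg)
#> # A tibble: 1 × 5
#>   offspring_id locus     expected_genome observed_allele observed_class
#>   <chr>        <chr>     <chr>           <chr>           <chr>
#> 1 JUV19        Re1Caga10 [L]             110             r_specific
```

Every son's paternal haplotype is identical (the clonal [L] genome) except
for one conflict: son JUV19 carries the father's R-specific allele 110 where
the [L] allele was expected — a genome-leakage event, flagged rather than
discarded.

The published cross table ships as a fixture; its totals are reproduced by
the summary stage:

```r
calls <- expand_cross_table(waterfrog_crosses())
glance(summarize_families(calls))
#> # A tibble: 1 × 7
#>   n_crosses n_offspring rr_daughters rl_sons sexed_offspring ...
#> 1        17         278           67     207             274
```

67 of 274 sexed offspring are RR daughters produced by hybrid fathers — the
clonal-[R] return of captured maternal genomes to the sexual species — and
`classify_gamete_profiles(calls)` identifies 9 [L]-only fathers, 2
amphispermic fathers and one [R]-only father.

`run_pipeline(genotypes, registry, pedigree, out_dir)` writes the full
report set (taxon calls, phased haplotypes, MLG clusters, gamete profiles,
leakage events, rf matrix, family summary, JSON manifest);
`inst/scripts/hemiphase.R` is a thin command-line wrapper
(`simulate` / `all`).

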