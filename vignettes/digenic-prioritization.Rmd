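---
title: "Trans digenic variant prioritization: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans digenic variant prioritization: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digenicscan)
```

## The inference the package implements

`digenicscan` formalizes a family-exome analysis for phenotypes that
defeat monogenic models. The disease model is digenic inheritance
(synergistic heterozygosity): two heterozygous variants in two distinct
genes of one pathway, one contributed by each parent, jointly causing the
phenotype. In a quartet with two affected children, the causal signature
is a pair of *shared monoallelic* variants in trans — each variant
heterozygous in every affected child, carried by exactly one parent — in
genes that co-occur in a biologically relevant gene set.

The pipeline runs stages in a fixed order and logs a funnel of surviving
counts:

1. autosomal filter (X/Y/MT excluded by default; the digenic signature of
   interest is autosomal, and hemizygous genotype codes would need a
   separate model);
2. region filter: `region_class` in {exonic, splicing} — coding regions
   and near exon-intron junctions;
3. rarity filter: the population allele frequency is missing (novel) or
   strictly `< 0.01`;
4. deleteriousness: strict majority vote over seven in-silico predictors;
5. shared-monoallelic segregation with origin by transmission;
6. trans pairing (maternal x paternal, distinct genes), gene-set
   restriction, ranking.

Stage order affects only the logged counts, not the result: the filters
are conjunctive, so the surviving pair set is order-invariant. Funnel
monotonicity over the variant-level stages is asserted at run time.

## The rarity rule

A variant passes when its frequency field is missing or strictly below
`rarity.max_af` (default 0.01). The default field is the **global**
database frequency, not the population-maximum. This is a deliberate
choice: a genuine digenic candidate can be markedly enriched in one
ancestry subset (global MAF 0.002 but subset MAF 0.02 for the canonical
KLB-type variant) and a popmax rule at 0.01 would discard it. Popmax mode
(`rarity.use_popmax`) remains available as a stricter option for cohorts
where ancestry-matched frequencies are trusted.

## The majority-vote deleteriousness classifier

Seven predictors vote: CADD, SIFT, PolyPhen-2, LRT, MutationTaster,
GERP++, PhyloP. Each raw score or categorical call maps to
damaging/benign/missing via per-predictor cutoffs; missing calls never
vote. The verdict is deleterious iff

* `n_damaging > n_informative / 2` (a tie is **not** a majority), and
* `n_informative >= vote.min_informative` (default 4 of 7).

The second clause is a conservatism device: a variant with one damaging
call and six missing would otherwise be "unanimously" damaging. Sparsely
annotated variants are dropped and flagged `insufficient_evidence` rather
than guessed.

The cutoffs (CADD phred ≥ 20, SIFT ≤ 0.05, PolyPhen-2 ≥ 0.446 — the
"possibly damaging" boundary —, LRT = "D", MutationTaster in {"A","D"},
GERP++ ≥ 2.0, PhyloP ≥ 1.5) are the tools' conventional published
operating points. They are defaults, not claims: all are overridable via
`vote.thresholds.*`, and the vote is symmetric in predictor identity, so
any recalibration only shifts counts.

## Segregation and phase by transmission

Phase is never taken from the VCF (phased separators are accepted and
ignored). Parental origin is re-derived from transmission: a child's
heterozygous allele is maternal iff the mother is a carrier and the father
is observed homozygous reference, paternal for the converse, ambiguous
otherwise. This is the only phasing a short-read family design supports
robustly, and it is exactly what makes a trans assignment possible.

Consequences of the strict rule, all configurable:

* **Missing genotypes disqualify** a variant for any pattern that needs
  them (no imputation). A quartet design has complete data; degrading
  gracefully under missingness is the permissive mode's job
  (`segregation.allow_other_parent_carrier`), which ignores the
  non-carrier parent's genotype at the cost of losing the guarantee that
  the other parent is truly non-carrier.
* **Both-parent carriers are ambiguous** and excluded from the
  shared-monoallelic list — origin cannot be assigned, so no trans claim
  is possible.
* **Unaffected siblings do not veto** shared monoallelic candidates
  (incomplete penetrance is the norm in digenic models — carrier parents
  are labelled unaffected), but they do veto compound-heterozygous pairs,
  mirroring standard recessive filtering.
* Same-gene cross-parental pairs are compound heterozygotes: they are
  reported by the recessive scan and deliberately excluded from digenic
  pairing to prevent double counting.

## Ranking

The rank score — mean over the pair's two variants of
`(n_damaging / n_informative) * (1 - af_global)`, missing AF treated
as 0 — is reporting convenience, not inference. The real selection is the
predicate chain; the score only orders survivors (descending, with
lexicographic gene-pair tie-breaking for determinism) and is excluded from
any validation claim.

## The synthetic family exome

Real data for this family design are restricted, so the package carries a
generator that emulates the statistical structure the analysis relies on:

* **Allele-frequency spectrum**: Beta(0.2, 6) truncated to
  `[1e-5, 0.5]`, heavily rare-skewed so the MAF filter is consequential.
  Founder genotypes are two independent Bernoulli(AF) alleles.
* **Transmission**: each child receives one allele per parent, uniform
  over the parent's two alleles, independent across variants. Loci are
  unlinked — no LD, no recombination map — because every downstream
  predicate is per-variant or per-pair; linkage would add nothing the
  pipeline could detect.
* **Annotation noise**: a causal variant draws a damaging call per
  predictor with sensitivity 0.9; background variants with false-damaging
  rate 0.1; calls go missing with probability 0.05. Raw scores are drawn
  uniformly from the damaging or benign side of each cutoff so the
  thresholding code path is genuinely exercised. Under the defaults the
  expected fraction of background variants reaching a deleterious verdict
  is the exact Binomial(7, 0.1) upper tail at 4, ≈ 0.27% — small but
  non-zero, which is what makes the funnel realistic.
* **The planted pair**: two new rare variants (AF ≤ 0.002, passing
  rarity by construction) in two distinct genes, variant A heterozygous in
  the mother only among founders, variant B in the father only; every
  affected child carries both, unaffected children at most one. Affection
  status is fully penetrant for double carriers and independent of
  background variants; carrier parents are labelled unaffected. The
  planted genes are embedded in a causal gene set alongside decoy sets.
* **Determinism**: a fixed seed makes the generator byte-identical,
  including its written files (the VCF header is fixed and date-free).

What the simulator does **not** model: sequence-level reads, per-gene
mutation-rate variation, population structure, annotation-density
differences between genes, and the correlation structure of real
predictor scores (calls are independent across predictors given causal
status; real predictors are correlated, so the real-data false-verdict
rate will differ from the binomial tail). Passing the benchmark therefore
demonstrates the *logic* of the pipeline — filters, segregation, pairing,
ranking, and their interaction — not calibrated performance on real
exomes. In particular the generator makes no attempt to reproduce the
shared-deleterious-variant counts a real exome yields (on the order of a
thousand shared deleterious variants before gene-set narrowing), which
depend on real annotation density.

## Numerical and interface choices

* Problem sizes used by the test suite and the acceptance script: 5,000
  background variants per simulated quartet, 100 seeds for recovery and
  transmission-fairness checks, 50,000 variants for the background-rate
  check, 50 random instances for oracle equivalence. These sizes give
  Monte-Carlo errors comfortably below the margins being tested while
  keeping a full run in the tens of seconds.
* Genotype codes are 0/1/2/NA after biallelic reduction of multiallelic
  sites (each alternate allele becomes its own record; other alternates
  count as reference). Downstream logic is purely carrier/non-carrier, so
  dosage against the focal allele is the right reduction, and splitting
  conserves per-sample total alt dosage.
* Coordinates are 1-based inclusive (VCF convention); the canonical key
  is `chrom:pos:ref:alt` after splitting. Inputs are assumed
  left-aligned/normalized; the package does not re-normalize indels.
* Config files are YAML with the dotted key groups named throughout the
  documentation (`rarity.*`, `vote.*`, `segregation.*`, `digenic.*`,
  `pipeline.*`); YAML was chosen as the most portable human-editable
  format in the R ecosystem. Every file-based run writes the resolved
  config next to the report for provenance.
* Degenerate inputs: an empty VCF produces an empty report with zero
  counts and a success status; a pedigree with no affected member warns
  and yields empty scans; a gene-set restriction against an empty
  collection is an error (silently keeping everything would defeat the
  stage's purpose).

## Known limitations

* X-linked and mitochondrial patterns are excluded by default rather than
  modelled; hemizygous codes would need their own segregation rules.
* The gene sets that matter in a real analysis (insulin/IGF1/FGF21
  signaling and related pathways) are supplied by the user; membership
  restriction is implemented, enrichment statistics are not — candidate
  narrowing here is a lookup, not a test.
* Compound-heterozygous detection relies on transmission phasing, so a
  parent-missing genotype removes the gene from comphet consideration.
* The ranking score is heuristic; treat report order as presentation, not
  evidence strength.
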