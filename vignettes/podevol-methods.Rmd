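---
title: "Methods: fixation analysis for serial-passage experimental evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixation analysis for serial-passage experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podevol)
```

## The problem

In a long-term serial-passage experiment, replicate clonal populations are
founded from one or two ancestral genotypes and resequenced at a handful of
timepoints. The analytical questions are: which variant calls are genuine
fixations rather than sequencing or mapping artifacts; what do those fixations
do to proteins; and do their effect-class composition, gene-level clustering,
and conservation properties show the signature of positive selection rather
than neutral accumulation?

`podevol` implements that analysis for a submerged-cultivation evolution
experiment on a filamentous fungus: eight populations from two founder
lineages (five from A, three from B), sampled at passages 75, 130, 200 and
268. Because clonal populations cannot purge a fixed allele, presence is
modelled as monotone in time: a fixation observed once is assumed present at
every later timepoint.

## Fixation filtering

Raw per-sample calls are reduced to candidate fixations by five exclusion
rules, applied in a fixed order (quality, founder support, multi-population
sharing, mask proximity, adjacency):

* **Quality** — keep calls with coverage ≥ 10 reads and allele frequency
  ≥ 80%, both inclusive.
* **Founder support** — a variant supported by ≥ 2 reads in the corresponding
  founder genotype is ancestral, not a fixation.
* **Multi-population sharing** — a site supported by ≥ 2 reads in more than
  one population while the founder has *zero coverage* there is treated as a
  systematic artifact; shared sites that the founder does cover are retained
  (genuine parallel fixations at the same site are possible and observed).
* **Mask proximity** — indels inside a low-complexity mask interval expanded
  by 10 bp on each side (inclusive) are discarded; SNVs are exempt.
* **Adjacency** — two same-population SNVs at adjacent sites are treated as
  one dinucleotide mutation event and both removed.

Each rule's predicate depends only on the raw evidence, never on another
rule's outcome, so the surviving set is order-invariant (the test suite
checks this by permuting the cascade); the order only decides which rule an
excluded call is attributed to in the audit trail. "Supported by at least two
reads" is read as *alt-allele-supporting* reads — depth alone cannot support
a variant. Indels are trimmed and left-aligned before any positional rule, so
filtering is representation-invariant. The quality thresholds are applied per
sample (whether the original analysis required 80% at one or all timepoints
is not documented; per-sample is the weaker and simpler reading, and the
monotone-presence reconciliation recovers any fixation that passes once).

## Timepoint reconciliation

A mutation is *verified* when the validation assay (Sanger resequencing in
the modelled experiment) confirms it at any timepoint; presence is then
imputed from the earliest evidence onward. Mutations confirmed nowhere are
*unverifiable* and excluded from every downstream statistic. A verified
mutation whose earlier assays are all uninformative has an unorderable
appearance passage (*time_unknown*): it counts in totals but not in the
accumulation regression. A sequencing presence pattern that loses a mutation
after its first appearance contradicts the clonal model and raises a
monotonicity warning rather than an error.

## Effect annotation

Variants are classified against GFF3 gene models on the founder genome:
coding SNVs in complete genes (proper start, terminal stop, length divisible
by three, no internal stop) become missense, nonsense or synonymous by
translating the affected codon on the gene's strand; coding indels become
frameshift or in-frame by length modulo 3, attributed to the leftmost
affected base of the left-aligned representation. SNVs in incomplete genes
are tagged `incomplete_gene`, positions between CDS segments `intronic`,
positions outside genes `intergenic`, and contigs without transferred
annotation `unaligned`. Two deliberate edge conventions: a substitution at a
terminal stop codon that preserves a stop is synonymous, and a stop-loss is
missense (no extra category is invented); a variant hitting overlapping genes
is reported under the most severe effect (nonsense > frameshift > missense >
in-frame > synonymous > intronic), with all hits retained in the audit trail.
The test suite checks the classifier against an independent oracle that
rebuilds the entire mutant genome, re-extracts and translates every protein
and diffs the products, and asserts strand-swap invariance.

## Context-matched permutation nulls

To ask whether protein-altering fixations are over-represented, the observed
SNV sets (85 in lineage A, 40 in B at the modelled scale) are re-thrown onto
their founder genomes 10,000 times and re-annotated. Each mutation is placed
uniformly at random among the genomic positions sharing its forward-strand
trinucleotide context, keeping its substituted base, so that mutational
opportunity (context composition) is held fixed. The empirical p-value is the
inclusive right tail, `#{null ≥ observed} / n_reps`; the add-one
(Davison–Hinkley) estimator is available via `estimator = "add_one"`.

Choices the original description leaves open, resolved here and testable
either way:

* **Undefined contexts** (contig edge, `N` in the window): the mutation is
  placed uniformly over all eligible positions, keeping replicate mutation
  counts exact.
* **Strand symmetrisation**: contexts are read on the forward strand and not
  collapsed to pyrimidine-centred classes; `collapse_strand = TRUE`
  implements the symmetrised alternative.
* **Collisions**: two mutations may land on one position in a replicate;
  at genome scale the effect is negligible and the exact-enumeration oracle
  covers the engine either way.
* **Alt-base identity** is preserved during re-throwing (effect classes
  depend on it); re-drawing from the observed spectrum would be an
  alternative the data do not distinguish.

The gene-level parallelism statistic is the number of genes carrying at
least two protein-altering (missense or nonsense) SNVs pooled across both
lineages; its null re-throws the A and B sets onto their genomes per
replicate. The engine is validated against exhaustive enumeration of all
placements on genomes small enough to enumerate, at 50,000 Monte Carlo
replicates within three binomial standard errors.

## Conservation and Miyata distances

Pairwise protein alignments against a diverged relative give each evolved
protein a conservation profile. A pair is a *reliable ortholog* when at most
20% of its alignment columns contain a gap (boundary inclusive). A column is
*conserved* iff both sequences carry the identical residue; the conserved
fraction is taken over columns where the focal protein has a residue, which
puts mutated-site lookups and the genome-wide background (62% in the modelled
data) on the same column universe. Both denominator conventions differ only
through focal-gap columns; the focal-residue denominator is used throughout.

The enrichment tests are exact binomial tests of the number of
mutation-carrying proteins with a reliable ortholog (against the genome-wide
reliable fraction, 4,713/10,230 at the modelled scale) and of the number of
mutated residues on conserved columns (against the 62% background). The
default is the *two-sided* exact test — the reported values this package
reproduces (0.000935, 0.04888, 0.003) are two-sided `binom.test` values, not
one-sided tails — with `alternative = "greater"` exposed for the right tail.

Physicochemical severity of replacements uses the Miyata distance,
`d(a,b) = sqrt((Δp/σp)² + (Δv/σv)²)`, recomputed from the Grantham polarity
and volume constants that distance is built on, with σ the standard deviation
across the 20 amino acids. The matrix is validated in the tests against an
independent `dist()` recomputation and its metric properties rather than a
keyed-in copy of the published table. Group means (experimental vs divergence
substitutions) are compared with a pooled-variance two-tailed t-test
(`welch = TRUE` for the unequal-variance form); two degenerate zero-variance
groups with equal means give p = 1 by convention.

## Evolutionary summaries

* **Fixation summary** — transition/transversion and effect-class tallies per
  lineage; percentage shares are rounded half-up to 1 decimal (whole percents
  for transition shares), matching the reporting convention of the modelled
  study (52/148 = 35.1% missense, 11/148 = 7.4% nonsense, 13/148 = 8.8%
  frameshift; transitions 62/85 = 73% and 21/40 = 53%).
* **dN/dS** — expected site counts by the equal-rates Nei–Gojobori variant:
  every CDS position distributes weight 1 over its three substitutions, so
  `sites_N + sites_S` equals the CDS length exactly (a tested invariant). A
  transition/transversion-weighted variant sits behind the `tstv` argument.
  Stop codons stay in the site universe (stop→stop is synonymous, stop→sense
  nonsynonymous). The neutral-expectation binomial test is two-sided by
  default. Under uniform placement of 1,000 SNVs over the CDS the estimator
  is calibrated to within ±0.1 of 1.
* **Accumulation regression** — the response is the per-interval fixation
  *rate* (new fixations / passages in the interval), regressed on the interval
  midpoint passage, pooled over populations; only a rate response can express
  a declining pace of fixation when sampling intervals are unequal. Noise-free
  constructed inputs are recovered exactly.
* **Passages per fixation** — `(populations × passages) / fixations`,
  reported raw and rounded (8 × 268 / 148 ≈ 14.5 → 14).
* **Mutator check** — fixed-effects two-way ANOVA of per-timepoint counts
  with population nested in lineage; calibrated on null simulations (type-I
  rate at α = 0.05 within [0.02, 0.09] over 100 datasets).

## The synthetic experiment generator

Every stage is exercised end-to-end on generated data, so the package needs
no external downloads. The generator emulates the modelled experiment's
design, not its sequences:

* Eight populations (5 A + 3 B), timepoints 75/130/200/268, fixations as a
  Poisson process at 0.07 per passage per population (~150 over the
  experiment), 125/148 of them SNVs, transition:transversion 2:1 (between the
  73% and 53% lineage shares), placement context-uniform.
* Gene models complete by construction (ATG + non-stop codons + stop), ~20%
  with one intron, strands random; masks inside intergenic spacers.
* Six parallel-target genes planted with the modelled hit pattern
  (2 nonsense / 1 nonsense + 2 missense / 6 frameshifts / 2 missense /
  2 nonsense + 1 missense / 7 missense), each hit in a distinct population.
* Planted artifacts, each violating exactly one filter: low-coverage calls,
  founder-supported variants, founder-uncovered multi-population sites,
  adjacent SNV pairs, masked-region indels.
* Ortholog alignments per gene with a configurable reliable fraction
  (0.575 given an ortholog, 0.8 ortholog probability ≈ 0.46 overall, the
  modelled genome-wide fraction) and 62% per-site conservation.

What the generator does **not** model: within-population dynamics (no
Wright–Fisher or clonal interference — fixations appear atomically, which is
exactly the monotone-presence assumption of the analysis), read-level error,
alignment/liftover failure beyond an `unaligned` pass-through tag, and real
mutational spectra beyond the ts:tv ratio. Passing tests therefore
demonstrate the *pipeline's* correctness and calibration on data meeting its
assumptions, not robustness to violations of those assumptions.

Default problem sizes in the tests (15–100 kb genomes, 10,000 permutation
replicates, 1,000-variant oracle comparisons, 100-dataset calibrations) were
chosen as the smallest scales at which the statistical checks have power;
all are configurable upward.

## Reproducibility

Every stochastic component takes an explicit seed. The pipeline
(`run_pipeline()`) derives one seed per stage from a single global seed via a
stable hash of the stage name, so stages can be re-run in isolation; the
manifest records stage seeds, input checksums and row counts. The pipeline is
single-threaded; determinism depends on the seed alone.

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(seed = 42), dir = "run")
make_report("run")
```
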