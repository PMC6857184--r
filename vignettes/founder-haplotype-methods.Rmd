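---
title: "Methods: pedigree-constrained founder-haplotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-constrained founder-haplotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

## The problem

A rare dominant disease mutation observed in a new family can descend from a
known founder or from an independent mutational event. The discriminating
evidence is the haplotype background: because the mutation sits on one
physical chromosome, the alleles of tightly linked markers on that
chromosome travel with it through the generations. `founderhap` recovers
that background from the unphased genotypes of a nuclear sibship, places it
in the haplotype spectrum of a reference population, and compares it with
named founder backgrounds. The motivating application is the *SOD1* p.A5V
(A4V) mutation in amyotrophic lateral sclerosis, for which distinct North
American and European founder backgrounds have been described; the packaged
marker panel spans chromosome 21 from *SOD1* to *SCAF4* (15 SNPs and one CA
microsatellite).

## Model and assumptions

**Zero recombination within the panel.** The panel covers a few hundred
kilobases transmitted across a single generation, so each offspring is
assumed to inherit one intact haplotype from each parent. Recombinant
offspring therefore surface as Mendelian inconsistencies rather than being
modelled; this is deliberate, since a single sibship carries no information
to place a crossover, and the error message names the marker and trio so
the user can subset the panel instead.

**Exact phase enumeration.** A phase solution assigns each founder an
ordered pair of haplotypes and each genotyped offspring a transmission
(paternal haplotype index, maternal haplotype index) such that every
genotype at every marker equals the multiset of transmitted alleles.
`enumerate_phasings()` returns *all* solutions: conditional on a
transmission vector the markers decouple, so consistent parental allele
assignments are enumerated per marker by constraint propagation and
combined as a Cartesian product; transmission vectors are enumerated
outermost. Founder haplotype pairs are unordered, so solutions are reported
in a canonical form (pairs sorted bytewise, transmission bits remapped;
bytewise rather than locale collation so canonical output is identical
across systems) and deduplicated. When a founder has no genotype of its
own, its two haplotype slots are exchangeable and the first offspring's
transmission bit on that side is pinned — a symmetry reduction that the
canonical form undoes. Untyped parents simply accumulate `NA` at positions
nothing forces. The enumeration is capped (default $10^6$ configurations)
because exactness, not scalability, is the point at panel scale (≤ 16
markers); a 4-allele microsatellite heterozygous throughout a sibship with
untyped parents can exceed the cap, and the error advises subsetting.
A genotype with a missing allele at a marker imposes no constraint there;
half-called genotypes (one known allele) are treated the same way, a
simplification that suits Sanger-typed panels where half-calls are rare.

**Carrier background.** Across solutions, `carrier_background()` collects
every founder haplotype that carries the mutant allele and is shared by all
named carriers. Carriers may include an ungenotyped obligate carrier (the
affected deceased father in the motivating pedigree), which restricts the
mutation to that parental lineage; solutions that place the mutation
elsewhere are discarded as incompatible with the carrier annotation.
Positions on which the surviving candidates disagree are reported as
MISSING rather than as an error: disagreement means the data do not force
the position, and a partially determined background is still informative
for founder comparison, which skips MISSING sites.

## Spectra, naming and classification

Reference panels are assumed phased (the 1000 Genomes phase 3 release is);
the package performs no statistical phasing of unrelated samples. Panel
markers absent from the VCF are dropped panel-wide, never per sample, so
haplotypes stay aligned — this mirrors moving from the 16-marker family
panel to the 14 SNPs available in reference data (`pop14` preset: all SNPs
minus the mutation site, microsatellite excluded, since reference panels
carry neither the private mutation nor fragment-length alleles).

Haplotypes are named by descending frequency rank, ties broken by the
bytewise order of the allele string so naming is deterministic; the suffix
`V` is reserved for the mutation-bearing variant of a named background
(`1V`), with `A` marking the wild-type variant in family reports.
Frequencies are kept as exact ratios internally and only rounded for
display. A reference haplotype is *compatible* with an unphased genotype
when one allele of every genotype pair matches it (missing genotypes match
anything); under a mutation constraint the recovered carrier background
must also equal the reference at every co-observed site, which is what
reduces the compatible set to a single background in an informative family.
Unresolved-phase literature genotypes (such as `C/G` entries for a single
reported case) are modelled as ambiguous allele sets; the default lenient
policy scores them as matching when the sets intersect, and the strict
policy never does — the founder tables expose both.

Mismatch counts are reported together with the number of co-observed sites
(`n_compared`); sites missing in either haplotype are skipped, so the
published comparisons resolve to 0 of 14 (family vs Swedish background,
rs202445 untyped in the published column) and 9 of 14 (North American vs
Swedish). The mutation site itself is included whenever both haplotypes
carry an allele there; `founder_table(exclude_ids = ...)` supports the
stricter convention of excluding it.

## Linkage disequilibrium

`pairwise_ld()` uses the standard two-locus definitions with major-allele
labelling (frequency ≥ 0.5, bytewise tie-break): $D = p_{AB} - p_A p_B$,
$r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, and $D' = |D|/D_{\max}$ with
$D_{\max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D > 0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ for $D < 0$. The sign of $D$ depends on the
arbitrary allele labelling, so only $r^2$ and $D'$ are reported by default.
Monomorphic markers take $D = r^2 = D' = 0$ by convention and are flagged;
haplotypes missing an allele at a pair are dropped for that pair only
(complete-case per pair).

Blocks are maximal contiguous runs of at least two markers in which *every*
within-run pair meets the threshold, found by greedy left-to-right maximal
extension — deterministic and disjoint by construction. The default metric
is $D'$ at 0.90: qualitative descriptions of "high LD" name no algorithm or
threshold, so the default is a package choice, configurable, and validated
against planted ground truth (a perfect-LD core between equilibrium flanks
is recovered exactly) rather than against any published block boundary.

## The synthetic-data generator

The generator emulates the data layout of a founder study, not its
population genetics: phased diploids drawn i.i.d. from a configured
haplotype spectrum, and one nuclear family in which the mutant allele is
implanted on the carrier parent's haplotype of a configured frequency rank,
offspring inheriting without recombination, genotypes returned with phase
stripped. The defaults are the study conditions: one reference population
of 102 diploids (204 chromosomes) and a sibship of four with an affected,
untyped carrier father. The default spectrum has eight haplotypes at
frequencies 0.45, 0.20, 0.12, 0.08, 0.06, 0.04, 0.03, 0.02 — stand-ins at a
realistic decay for a regional spectrum whose exact values are not
published as numbers; haplotype 1 is the Iberian founder background and
haplotype 2 the North-American-style background from the packaged table,
the rest single-site variants. These are configuration, not constants.
Markers outside the reference spectrum (the mutation site, the
microsatellite) receive uniform per-haplotype draws. Everything is
seed-deterministic end to end, and the seed is recorded in the VCF header
and the truth record.

What the generator does *not* reproduce: realistic LD decay with distance,
genotyping error structure (a uniform per-allele error knob exists only to
exercise the Mendelian-inconsistency paths), population substructure, or
recombination. Passing tests on synthetic data therefore demonstrate the
correctness of the algorithms under the stated model, not robustness to
those real-data features.

The `emulate_study()` preset adds an identifiability contract: seeds are
advanced deterministically until the drawn family has at least one carrier
offspring, a tractable enumeration, and a fully forced carrier background —
the situation of the motivating pedigree, where one sib heterozygous only
at the mutation site pins every position. Rejection checks only
*completeness* of the recovered background, never its agreement with the
implanted truth, so recovery tests remain meaningful.

## Numerical and design notes

* Frequencies and LD statistics are plain double arithmetic; comparisons in
  block detection use a $10^{-12}$ slack so a threshold of exactly 1.0
  accepts computed values of 1.
* Validation sizes: the oracle-equivalence property runs hundreds of random
  families at ≤ 5 markers and ≤ 6 members, where the naive
  $2^{\text{het sites}}$ oracle is still cheap; planted-truth recovery uses
  200 study-scale replicates; spectrum calibration uses 200 replicates of
  102 diploids, judged against three binomial standard errors
  ($\mathrm{SE} = \sqrt{p(1-p)/204}$) pooled over all frequency estimates.
* A fully homozygous offspring is *not* informationally inert: it proves
  one parental allele pairing and can shrink the solution set. The
  invariant tested is the correct weaker statement — duplicating an
  existing homozygous offspring changes nothing.
* Marker order is authoritative from the panel definition, never re-sorted
  by position; genomic coordinates are optional metadata (`NA` in the
  packaged panel) because every computation is order-based.
* The packaged panel stores one observed and one alternate allele per SNP;
  where the published family data show only a single allele the alternate
  is a plausible stand-in needed by the simulator, and the packaged
  founder table is the published data proper.

## Limitations

Single nuclear sibships only (no multi-generation pedigrees, no likelihood
or LOD support); no statistical phasing or imputation of unrelated samples;
no founder-age or coalescent dating; no Gabriel-style confidence-interval
block definition. Reference-panel analyses reproduce published haplotype
counts only when run on the corresponding reference data, which the user
supplies as a VCF slice.
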