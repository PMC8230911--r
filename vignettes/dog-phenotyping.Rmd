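---
title: "Predicting visible traits of dogs from a 21-marker forensic panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting visible traits of dogs from a 21-marker forensic panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogphen)
```

## The problem

When canine DNA from a crime scene matches no reference sample, a
description of the dog it came from — "a large black dog with a long,
smooth coat" — is still valuable investigative intelligence. Forensic DNA
phenotyping infers such externally visible characteristics directly from
genotypes. `dogphen` implements this for six trait categories that an
untrained eyewitness can recognise: coat colour, coat pattern, coat
structure, body size, ear shape and tail length, using a panel of 21
published markers (15 SNPs and six insertion/deletion markers, of which
three are SINE insertions) in the genes *MC1R*, *CBD103*, *ASIP*,
*TYRP1*, *MLPH*, *MITF*, *PMEL*, *PSMB7*, *RSPO2*, *FGF5*, *KRT71*, the
T-Box transcription factor gene, *IGF2BP2* (marker BICFPJ1062878) and
*IGF1R*.

## The genetic model

Coat colour and pattern follow the classical locus nomenclature, with an
explicit epistatic hierarchy:

* **E-locus (*MC1R*)** is epistatic to everything below it. An `e/e` dog
  produces only phaeomelanin: its coat is red/yellow/cream regardless of
  the K- and A-locus genotypes. The `E^m` allele (dominant over `E`) adds
  a melanistic mask. Two SNPs jointly type this locus; since phase between
  them is unrecoverable from Sanger data, the engine counts `e` alleles
  from MC1R_306ter and assigns `E^m` only to the non-`e` dosage. This
  shortcut reproduces every multi-allele configuration the locus can
  realise (a dog with one `e` and one M264V `G` is `E^m/e`).
* **K-locus (*CBD103*)**: a dominant `K^B` forces a solid eumelanin coat
  and masks the A-locus; only `k^y/k^y` dogs express ASIP. Two redundant
  markers (a 3-bp microINDEL and a SNP) type the locus; they must agree,
  and disagreement sets a conflict flag (the microINDEL call is then
  used). `K^B/k^y` dogs could be brindled, which this panel cannot
  genotype, so such predictions carry a `possible_brindle` caveat.
* **A-locus (*ASIP*)**, expressed only on `k^y/k^y`: allele hierarchy
  `A^y` (fawn/sable) > `a^w` (wild-type agouti) > `a^t` (tan points) >
  `a` (recessive black), typed by four markers. No haplotyping procedure
  exists for unphased data, so the engine uses a dominance shortcut: any
  `A^y`-defining variant proves `A^y`; otherwise the SINE dosage (`a^t`)
  and the R96 variant dosage (`a`) bound which haplotypes can exist, and
  the top-ranked provable allele is expressed. Combinations that remain
  ambiguous are reported as a candidate set rather than guessed. The
  shortcut is exact for every genotype composed of the four canonical
  haplotypes (the decision-table test enumerates all of them).
* **B-locus (*TYRP1*)** renders eumelanin brown when **two** recessive
  alleles are present in any combination across the two typed variants
  (`b^s/b^s`, `b^s/b^d`, `b^d/b^d`), assuming the two variants never share
  a haplotype (stated in the derivation chain). A third published brown
  allele (`b^c`, S41C) is *not* in the panel: a reconstruction of `B/B` or
  `B/b` could therefore hide an untested brown allele, and every such
  prediction carries the `untested_allele_bc` caveat. This is the panel's
  documented coat-colour failure mode.
* **D-locus (*MLPH*)** dilutes both pigments when `d/d`: black becomes
  blue, brown becomes isabella. The sources name no dilute phenotype for
  an `e/e` coat; the label "pale cream" used here for `e/e` + `d/d` is
  this package's own wording.
* **S (*MITF*)**: spotting from the SINE insertion — `S/S` solid/minimal
  white, `S/S^p` pseudo-irish, `S^p/S^p` piebald/extreme white. The
  associated MITF SNP is secondary evidence of unclarified dominance: it
  cross-checks the SINE call and flags disagreement, but never overrides
  it, and is not used alone.
* **M (*PMEL*)**: semi-dominant merle (`M/m` merle, `M/M` mainly white).
  On an `e/e` coat the pattern is invisible; the engine suppresses it and
  attaches the `hidden_merle` caveat.
* **H (*PSMB7*)**: harlequin, expressed only on a merle background. Its
  behaviour in the `H/H` state is undescribed; `H/H` is treated like
  `H/h`.

The remaining traits are single- or three-marker rules: *FGF5* hair
length (short dominant), *RSPO2* furnishings (insertion dominant),
*KRT71* curl (semi-dominant: `A/G` wavy), the T-Box mutation for bobtail
(dominant, homozygous-lethal — an observed `G/G` is reported inconclusive
with a `lethal_genotype_observed` caveat), the ear-shape marker
(unclarified dominance: heterozygotes are genuinely ambiguous and are
reported with both values), and the IGF1R size SNP ("rather small"
vs. "rather tall"; the dominance annotation sits on the `A` allele, so
heterozygotes are called rather small).

Nose and eye colour are deliberately not predicted: the typed B-locus
model cannot explain the documented case of an `e/e`, `B/b^s` dog with
brown nose leather, so any rule would be a guess.

### Missing data

Failed sequencing is a first-class state, not an error. Each predictor
enumerates the completions a missing locus could take: if every
completion yields the same value, the prediction stays `determined` and
the derivation chain names the overriding locus (e.g. ASIP unreadable but
irrelevant under `K^B/K^B` or `e/e`); otherwise the finite value set is
reported as `ambiguous`. `inconclusive` means a rule fired but was
uninformative; `not_evaluable` means no rule could fire.

## Trace calling

Traces are modelled at the base-call level — a primary and a secondary
call string standing in for a chromatogram — not as raw signal. For SNPs,
the trace is anchored to the reference context by exact flank match
(default 10 bases each side, with no secondary peaks inside the anchors);
a clean call gives a homozygote, a primary+secondary pair matching both
allele states a heterozygote.

Heterozygous insertions (the three SINEs, the 167-bp *RSPO2* insertion
and the two 3-bp microINDELs) co-amplify a short and a long allele whose
sequences run out of phase downstream of the insertion point.
`resolve_superposition()` locates the divergence point by exact prefix
match (left-aligned, shifting right automatically when the inserted block
begins with the bases that follow the insertion site), then checks each
downstream position against the base multiset contributed by the two
alignments. A trace is heterozygous iff every position shows exactly the
expected one- or two-base set; homozygous iff it matches one allele with
no secondary peaks; otherwise `inconsistent`.

Numerical choices: mismatch tolerance defaults to **0** — the callers
fail loudly rather than rescue a dubious trace, which is the right bias
for forensic use (a config knob exists). A trace must cover at least
**15** evaluable positions at or after the divergence point, otherwise it
is reported `insufficient` and becomes a MISSING call; this window is an
engineering choice, no published value exists. Orientation is explicit
metadata (primers fix it in practice); reverse traces are
reverse-complemented before calling, and calls are strand-invariant by
property test.

The bundled reference contexts are *synthetic* stand-ins of realistic
length (the true amplicon sequences are not reproducible from available
text); they are clearly labelled as such in the panel FASTA's file name.

## The simulator and what it does (not) show

`simulate_cohort()` draws genotypes under Hardy–Weinberg equilibrium,
independently across loci. Multi-marker loci are drawn as locus
haplotypes and expanded into marker states, so redundant markers stay
consistent — drawing each marker independently would flag a spurious
conflict in almost every dog. T-Box `G/G` draws are rejected and
resampled, so configured frequencies are pre-selection frequencies.

Observed phenotypes come from a vectorized "ground-truth twin" of the
rule engine (an independent implementation, which is what makes the
zero-noise closure test meaningful) plus four documented exception
channels, each with a configurable probability:

| rate | mechanism | default |
|------|-----------|---------|
| `p_bc` | a wild-type-genotyped TYRP1 haplotype secretly carries the untested `b^c` brown allele | 0.05 |
| `p_ancestral_bobtail` | a long-tail genotype is bobtailed via a non-T-Box mechanism (breed-specific) | 0.10 |
| `p_docked` | a genetically long tail was cropped; the observation is recorded not assessable | 0.05 |
| `p_ear_drop_given_het` | a heterozygous ear-marker dog shows drop ears | 0.50 |
| `p_size_misclass` | observed size class contradicts IGF1R | 0.30 |

Defaults mirror the documented failure rates where those exist (three of
ten tail-test dogs discordant; three of six ear heterozygotes with drop
ears; three of ten size mismatches) and plausible small values elsewhere.
Default allele frequencies are plausible for a mixed European companion
population (merle, harlequin and bobtail alleles rare; spotting and brown
alleles common); none of these is tuned against test outcomes.

What the simulator does **not** emulate: breed structure and kinship,
linkage between loci, allele frequencies of any real population,
quality-dependent call errors, or mixtures/contamination. A green test
suite therefore shows the pipeline is internally consistent and handles
the documented discordance mechanisms — not that the per-trait accuracies
would transfer to an arbitrary real population.

## Validation cohorts

The published study deposits no per-sample genotype tables, so
`validation_cohorts()` *reconstructs* its cohorts: minimal genotypes
consistent with the narrated compositions, named samples and discordance
counts — the 12-dog pilot set (252 attempted genotypes; three markers
monomorphic across the pilot), the 16-dog coat-colour set (12/16 colour
concordance with exactly the four named TYRP1-discordant dogs, three
failed ASIP SINE calls rescued by epistatic overrides, six heterozygous
`b^s` dogs, three unexpressed `K^B/k^y` brindle candidates, one dog with
both MITF markers failed), the four 10-dog marker-test sets (tail 7/10
with the three named bobtailed-breed dogs, ears 2 concordant + 1
discordant + 6 ambiguous heterozygotes + 1 failed, size 7/10, structure
10/10), and the 9-dog blind set (189 genotypes, none missing; one triple
identical at every marker except the ear marker; one cropped tail scored
as not assessable). Each fixture sample carries a paraphrased provenance
note; whether the published 12/16 figure counts colour alone or colour
and pattern jointly is not fully explicit, and the fixture is built so
that colour-alone scoring reproduces it.

## Scoring conventions

Per-trait accuracy is matches / (matches + mismatches). Ambiguous
predictions (the heterozygous ear marker) are excluded from the
denominator and reported as their own class — consistent with treating
heterozygotes as "no clear interpretation" and computing the 60%
heterozygosity rate separately. Cropped or docked observations score
`not_assessable_phenotype`, not `mismatch`: an artificially altered body
part is a non-genetic discrepancy.

## Problem sizes used by the checks

The test suite enumerates the full coat-colour genotype space
(6 × 3 × 10 × 6 × 3 = 3240 locus-genotype combinations) against an
independent flat truth table, runs 1000 random superposition instances
against a brute-force trace oracle, closes the loop on a 200-dog
zero-noise cohort, and recovers the exception-channel rates on a 5000-dog
cohort within three binomial standard errors. These sizes give stable
binomial checks at desk scale.

## Known limitations

* Brindle (`K^br`) and merle subtypes (cryptic/dilute/double) are not
  genotyped or discriminated; quantitative size is out of scope.
* One marker per trait for size, ears and tail is intrinsically weak;
  the ear marker especially is reported ambiguous for every heterozygote.
* The unphased A-locus shortcut can return candidate sets (never a wrong
  single value) for genotypes that are not composed of the four canonical
  haplotypes.
* Identikit texts are structured descriptions, not sketches.
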