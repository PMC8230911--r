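# dogphen

Forensic DNA phenotyping of domestic dogs: predicting externally visible
traits from a 21-marker genotyping panel.

When canine DNA recovered from a crime scene (hairs on a car seat, saliva
on clothing, evidence from a bite attack) matches no reference dog, STR
individualization is a dead end — but the DNA can still describe the dog
it came from. `dogphen` turns genotypes at 21 published phenotype markers
(15 SNPs and six insertion/deletion markers, three of them SINE
insertions, in *MC1R*, *CBD103*, *ASIP*, *TYRP1*, *MLPH*, *MITF*, *PMEL*,
*PSMB7*, *RSPO2*, *FGF5*, *KRT71*, the T-Box gene, *IGF2BP2* and
*IGF1R*) into predictions for six eyewitness-recognisable trait
categories — coat colour, coat pattern, coat structure, body size, ear
shape, tail length — and assembles them into a standardized "identikit"
description.

## The model

Coat colour and pattern are computed through the classical dominance
hierarchy of the pigmentation loci:

* **E (MC1R)** — epistatic to all loci below: *e/e* ⇒ phaeomelanin coat
  (red/yellow/cream) regardless of K and A; *E^m* adds a melanistic mask.
* **K (CBD103)** — *K^B* dominant ⇒ solid eumelanin, A-locus masked;
  only *k^y/k^y* expresses ASIP. *K^B/k^y* may be brindle (not typed →
  caveat).
* **A (ASIP)** — allele series *A^y* (fawn/sable) > *a^w* (agouti) >
  *a^t* (tan points) > *a* (recessive black), resolved from four
  unphased markers by an exact dominance shortcut.
* **B (TYRP1)** — eumelanin turns brown iff two recessive alleles occur
  in any combination across *b^s* and *b^d*; *B/B* and *B/b*
  reconstructions carry an untested-*b^c* caveat (the panel's documented
  brown-prediction failure mode).
* **D (MLPH)** — *d/d* dilutes black → blue, brown → isabella.
* **S (MITF)**, **M (PMEL)**, **H (PSMB7)** — white spotting series,
  (hidden) merle, and harlequin-on-merle pattern modifiers.

Coat structure combines *FGF5* (length), *KRT71* (curl, semi-dominant)
and *RSPO2* (furnishings); tail, ears and size are single-marker rules
including the lethal homozygous bobtail genotype and the genuinely
ambiguous heterozygous ear marker. Sanger-style traces — including
out-of-phase superposed traces of heterozygous insertions — are called at
the base-call level by `call_profile()` / `resolve_superposition()`.
Failed genotypes are carried as MISSING and predictions degrade
gracefully (`determined` → `ambiguous` → `inconclusive` →
`not_evaluable`), naming the epistatic override whenever a missing locus
turns out not to matter. A seeded simulator generates cohorts under
Hardy–Weinberg equilibrium with the four documented discordance channels
(hidden TYRP1 *b^c*, breed-specific bobtails, docking/cropping, ear
heterozygosity, size misclassification).

## Worked example

```r
library(dogphen)
panel <- load_panel()          # bundled 21-marker panel
panel
#> dog_panel 'canine-21 v1': 21 markers (15 SNP, 6 INDEL-type of which 3 SINE)
#> locus order: E > K > A > B > D > S > M > H

cohorts <- validation_cohorts(panel)   # reconstructed study cohorts
dog <- cohorts$blind$profiles[[2]]     # blind-test dog D4926
predict_all(dog, panel)
#> dog_identikit D4926
#>   black with tan points; minimal white spotting; long, smooth hair, no furnishings; long tail; drop ears; rather tall
#>   coat_colour: black [determined] caveats: untested_allele_bc
#>   coat_pattern: tan_points+minimal_white [determined]
#>   coat_structure: long+smooth+no_furnishings [determined]
#>   tail_length: long_tail [determined] caveats: possible_docking,possible_ancestral_bobtail
#>   ear_shape: drop [determined] caveats: possible_cropping
#>   body_size: rather_tall [determined]
```

The identikit line is the composite description an investigator would
use. Each trait carries a certainty grade and caveat codes: here the
black coat could in principle hide an untested brown allele
(`untested_allele_bc`), and the long tail could have been docked
(`possible_docking`) or be a breed-specific bobtail
(`possible_ancestral_bobtail`).

Scoring a cohort against observed phenotypes:

```r
preds <- lapply(cohorts$tail_length$profiles, predict_all, panel = panel)
scored <- score_cohort(preds, cohorts$tail_length$phenotypes)
scored$accuracy[scored$accuracy$trait == "tail_length", ]
#>         trait match mismatch ambiguous inconclusive not_assessable not_evaluable accuracy
#> 4 tail_length     7        3         0            0              0             0      0.7
```

Seven of the ten tail-test dogs are concordant (accuracy 0.7); the three
mismatches are the bobtailed-breed dogs that lack the T-Box mutation.
`render_heatmap()` writes the sample × trait outcome grid as TSV (and
optionally PNG).

A command-line interface wraps the same functions:

```sh
dogphen fixtures --out-dir fx                # emit the validation cohorts
dogphen predict  --genotypes fx/blind_genotypes.tsv --out-dir out
dogphen evaluate --genotypes fx/tail_length_genotypes.tsv \
                 --phenotypes fx/tail_length_phenotypes.tsv --out-dir out
dogphen simulate --n 500 --seed 7 --out-dir sim
```

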