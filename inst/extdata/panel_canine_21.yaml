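# Canine visible-trait marker panel: 21 markers (15 SNPs, 6 insertion/
# deletion markers of which 3 are SINE insertions) covering six trait
# categories. Allele symbols use ASCII-caret superscripts (E^m, K^B, S^p).
# Package convention: the white-spotting-associated allele of MITF_SNP is
# stored as "S^p" so the two alleles of that marker carry distinct symbols.
# Dominance tokens: dominant | recessive | semi_dominant | unclarified.
# Coordinates are 1-based CanFam3.1 and optional; only IGF1R has one.
# Reference contexts (synthetic stand-ins for the amplicon sequences) live
# in the companion FASTA; indel markers name the allele carried by the
# insertion-bearing ("long") sequence.
version: "canine-21 v1"
locus_order: [E, K, A, B, D, S, M, H]
contexts_fasta: panel_contexts_synthetic.fasta
markers:
  - marker_id: MC1R_306ter
    locus: E
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "e", state: "T", dominance: recessive, phenotype: "red, yellow, cream, white"}
      - {name: "E", state: "C", dominance: dominant, phenotype: "black, brown"}
  - marker_id: MC1R_M264V
    locus: E
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "E", state: "A", dominance: recessive, phenotype: "no melanistic mask (black, brown)"}
      - {name: "E^m", state: "G", dominance: dominant, phenotype: "melanistic mask (black, brown)"}
  - marker_id: CBD103_S54
    locus: K
    trait_category: coat_colour
    marker_type: microINDEL
    long_allele: "k^y"
    alleles:
      - {name: "k^y", state: "GGG", dominance: recessive, phenotype: "yellow - expression of agouti alleles"}
      - {name: "K^B", state: "DelGGG", dominance: dominant, phenotype: "black, brown, blue"}
  - marker_id: CBD103_S53
    locus: K
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "k^y", state: "G", dominance: recessive, phenotype: "yellow - expression of agouti alleles"}
      - {name: "K^B", state: "C", dominance: dominant, phenotype: "black, brown, blue"}
  - marker_id: ASIP_S82
    locus: A
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "A^y", state: "T", dominance: dominant, phenotype: "fawn/sable"}
      - {name: "a^w", state: "G", dominance: recessive, phenotype: "wild type/agouti (black, brown)"}
  - marker_id: ASIP_H83
    locus: A
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "A^y", state: "A", dominance: dominant, phenotype: "fawn/sable"}
      - {name: "a^w", state: "G", dominance: recessive, phenotype: "wild type/agouti (black, brown)"}
  - marker_id: ASIP_SINE
    locus: A
    trait_category: coat_colour
    marker_type: SINE
    long_allele: "a^t"
    alleles:
      - {name: "a^t", state: "SINE", dominance: recessive, phenotype: "tan points (black, brown), tricolour"}
      - {name: "a^w", state: "no SINE", dominance: recessive, phenotype: "wild type/agouti (black, brown)"}
  - marker_id: ASIP_R96
    locus: A
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "a^t", state: "C", dominance: recessive, phenotype: "tan points (black, brown), tricolour"}
      - {name: "a", state: "T", dominance: recessive, phenotype: "recessive black"}
  - marker_id: TYRP1_Q331ter
    locus: B
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "B", state: "C", dominance: dominant, phenotype: "black"}
      - {name: "b^s", state: "T", dominance: recessive, phenotype: "brown"}
  - marker_id: TYRP1_345delP
    locus: B
    trait_category: coat_colour
    marker_type: microINDEL
    long_allele: "B"
    alleles:
      - {name: "B", state: "CCT", dominance: dominant, phenotype: "black"}
      - {name: "b^d", state: "DelCCT", dominance: recessive, phenotype: "brown"}
  - marker_id: "MLPH_157471_c.-22G>A"
    locus: D
    trait_category: coat_colour
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "D", state: "G", dominance: dominant, phenotype: "not diluted pigmentation"}
      - {name: "d", state: "A", dominance: recessive, phenotype: "diluted pigmentation"}
  - marker_id: MITF_SNP
    locus: S
    trait_category: coat_pattern
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "S", state: "A", dominance: unclarified, phenotype: "solid coloured, minimal white spotting"}
      - {name: "S^p", state: "G", dominance: unclarified, phenotype: "white spotting"}
  - marker_id: MITF_INS
    locus: S
    trait_category: coat_pattern
    marker_type: SINE
    long_allele: "S^p"
    alleles:
      - {name: "S", state: "no SINE", dominance: semi_dominant, phenotype: "solid coloured, minimal white spotting"}
      - {name: "S^p", state: "SINE", dominance: semi_dominant, phenotype: "white spotting (piebald); S/S^p pseudo irish spotting"}
  - marker_id: PMEL
    locus: M
    trait_category: coat_pattern
    marker_type: SINE
    long_allele: "M"
    alleles:
      - {name: "M", state: "SINE", dominance: semi_dominant, phenotype: "merle; M/m mild merle"}
      - {name: "m", state: "no SINE", dominance: recessive, phenotype: "no merle"}
  - marker_id: PSMB7
    locus: H
    trait_category: coat_pattern
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "H", state: "G", dominance: dominant, phenotype: "harlequin"}
      - {name: "h", state: "T", dominance: recessive, phenotype: "no harlequin"}
  - marker_id: FGF5
    locus: n.a.
    trait_category: coat_structure
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "G", state: "G", dominance: dominant, phenotype: "short hair"}
      - {name: "T", state: "T", dominance: recessive, phenotype: "long hair"}
  - marker_id: RSPO2
    locus: n.a.
    trait_category: coat_structure
    marker_type: intermediate_INDEL
    long_allele: "Ins"
    alleles:
      - {name: "noIns", state: "no Ins", dominance: recessive, phenotype: "no furnishings"}
      - {name: "Ins", state: "Ins", dominance: dominant, phenotype: "furnishings"}
  - marker_id: KRT71
    locus: n.a.
    trait_category: coat_structure
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "A", state: "A", dominance: semi_dominant, phenotype: "smooth coat; A/G wavy coat"}
      - {name: "G", state: "G", dominance: semi_dominant, phenotype: "curly coat"}
  - marker_id: T-Box_C295G
    locus: n.a.
    trait_category: tail_length
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "G", state: "G", dominance: dominant, phenotype: "bobtail"}
      - {name: "C", state: "C", dominance: recessive, phenotype: "long tail"}
  - marker_id: BICFPJ1062878
    locus: n.a.
    trait_category: ear_shape
    marker_type: SNP
    variant_offset: 26
    alleles:
      - {name: "G", state: "G", dominance: unclarified, phenotype: "non drop ears"}
      - {name: "A", state: "A", dominance: unclarified, phenotype: "drop ears"}
  - marker_id: IGF1R
    locus: n.a.
    trait_category: body_size
    marker_type: SNP
    chrom: "3"
    pos: 41849479
    variant_offset: 26
    alleles:
      - {name: "G", state: "G", dominance: recessive, phenotype: "rather tall"}
      - {name: "A", state: "A", dominance: dominant, phenotype: "rather small"}
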