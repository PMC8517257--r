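# Statin ADR variant panel: seven SNPs with literature-pinned genetic models.
# `protective` lists the genotype classes (sorted allele strings) carrying the
# better-response orientation used by the risk score; `default_maf` is a
# realistic white-European minor allele frequency used by the simulator.
variants:
  - rsid: rs1128503
    gene: ABCB1
    chrom: "7"
    pos: 87179601
    major_allele: C
    minor_allele: T
    genetic_model: dominant
    protective: [CT, TT]
    default_maf: 0.42
    default_effect: 0.0
  - rsid: rs1045642
    gene: ABCB1
    chrom: "7"
    pos: 87138645
    major_allele: T
    minor_allele: C
    genetic_model: recessive
    protective: [CC]
    default_maf: 0.48
    default_effect: 0.09
  - rsid: rs4149056
    gene: SLCO1B1
    chrom: "12"
    pos: 21331549
    major_allele: T
    minor_allele: C
    genetic_model: recessive
    protective: [CC]
    default_maf: 0.16
    default_effect: 0.0
  - rsid: rs2306283
    gene: SLCO1B1
    chrom: "12"
    pos: 21329738
    major_allele: A
    minor_allele: G
    genetic_model: dominant
    protective: [AG, GG]
    default_maf: 0.37
    default_effect: 0.0
  - rsid: rs12975366
    gene: LILRB5
    chrom: "19"
    pos: 54756955
    major_allele: T
    minor_allele: C
    genetic_model: dominant
    protective: [CT, CC]
    default_maf: 0.40
    default_effect: 0.04
  - rsid: rs2740574
    gene: CYP3A4
    chrom: "7"
    pos: 99382096
    major_allele: A
    minor_allele: G
    genetic_model: recessive
    protective: [GG]
    default_maf: 0.08
    default_effect: 0.0
  - rsid: rs776746
    gene: CYP3A5
    chrom: "7"
    pos: 99270539
    major_allele: G
    minor_allele: A
    genetic_model: dominant
    protective: [AG, AA]
    default_maf: 0.07
    default_effect: 0.0
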