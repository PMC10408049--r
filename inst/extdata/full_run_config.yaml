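# Template for the full caffeine -> neuropsychiatric-disorder run.
#
# Fill in the paths below with the real inputs before running:
#   * exposure: plasma caffeine GWAS associations for the CYP1A2/AHR
#     regions (SD units), e.g. extracted from the published supplementary
#     association tables.
#   * outcomes: per-disorder GWAS summary statistics; each outcome may
#     combine a consortium GWAS with an independent biobank cohort, which
#     are meta-analyzed per variant before estimation.
#   * ld: signed correlation matrix over the instrument variants,
#     estimated from a European-ancestry reference panel (e.g. the
#     1000 Genomes EUR subsample), TSV with rsid header row and column.
#
# Expected reproduction tolerances for the published analysis: odds
# ratios to 3 decimals, I-squared to the nearest percent.
#
# Run with:
#   Rscript -e 'cismr::run_pipeline_file("full_run_config.yaml", out_dir = "results")'

exposure:
  path: data/exposure_caffeine.tsv
  trait: plasma caffeine
  units: SD
  # column_map: {rsid: SNP, ea: A1, oa: A2, beta: b, se: SE, pval: p}

outcomes:
  anorexia_nervosa:
    trait: anorexia nervosa
    sources:
      - path: data/outcome_anorexia_pgc.tsv
        name: PGC
      - path: data/outcome_anorexia_finngen.tsv
        name: FinnGen
  bipolar_disorder:
    trait: bipolar disorder
    sources:
      - path: data/outcome_bipolar_pgc_ukb.tsv
        name: PGC+UKB
      - path: data/outcome_bipolar_finngen.tsv
        name: FinnGen
  major_depressive_disorder:
    trait: major depressive disorder
    sources:
      - path: data/outcome_mdd_pgc_ukb.tsv
        name: PGC+UKB
      - path: data/outcome_mdd_finngen.tsv
        name: FinnGen
  schizophrenia:
    trait: schizophrenia
    sources:
      - path: data/outcome_scz_pgc.tsv
        name: PGC
      - path: data/outcome_scz_finngen.tsv
        name: FinnGen

ld: data/ld_eur_instruments.tsv

# GRCh37 gene coordinates with 100 kb flanks
regions:
  - name: CYP1A2
    chrom: "15"
    start: 75041185
    end: 75048543
    flank: 100000
  - name: AHR
    chrom: "7"
    start: 17338246
    end: 17385776
    flank: 100000

selection:
  p_threshold: 5.0e-5       # ~ Bonferroni 0.05 / 955 region variants
  clump_r2: 0.3
  clump_window_kb: 10000
  m_total: 955              # FIQT test count: variants measured in-region

eaf_band: 0.08
fiqt: true

leads:
  - rs2472297   # CYP1A2
  - rs4410790   # AHR

seed: 1
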