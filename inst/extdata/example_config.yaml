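# Example pipeline configuration: a synthetic cohort with the size and
# phenotype mix of a Swedish child-twin registry sample (4,767 MZ and
# 5,580 same-sex DZ pairs; prevalences and univariate variance components
# from published summary tables). Cross-trait rc/re values are not
# published; the shipped defaults (rc = 0, small re) are arbitrary.
spec:
  n_mz: 4767
  n_dz: 5580
  traits:
    - {name: clinical_autism, a2: 0.90, c2: 0.0, K: 0.016}
    - {name: clinical_adhd,   a2: 0.80, c2: 0.0, K: 0.043}
    - {name: epilepsy,        a2: 0.61, c2: 0.0, K: 0.012}
    - {name: asthma,          a2: 0.68, c2: 0.15, K: 0.134}
    - {name: constipation,    a2: 0.51, c2: 0.0, K: 0.062}
  cross:
    "clinical_autism:epilepsy":     {ra: 0.50, re: 0.15}
    "clinical_autism:asthma":       {ra: 0.15, re: 0.05}
    "clinical_autism:constipation": {ra: 0.31, re: 0.05}
    "clinical_adhd:epilepsy":       {ra: 0.25, re: 0.10}
    "clinical_adhd:asthma":         {ra: 0.15, re: 0.08}
    "clinical_adhd:constipation":   {ra: 0.20, re: 0.08}
  atac:
    autism: {source_trait: clinical_autism}
    adhd:   {source_trait: clinical_adhd}
exposures:
  - clinical_autism
  - clinical_adhd
  - subclinical_autism
  - subclinical_adhd
outcomes:
  - epilepsy
  - asthma
  - constipation
alpha: 0.05
bonferroni_m: 13
bivariate_method: ml
exclude_clinical: false
seed: 20230421
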