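# Default population for the synthetic meta-analytic corpus generator.
#
# The population mirrors the three-factor measurement structure of the
# TAS-20 (DIF-DDF-EOT) with factor correlations at the meta-analytically
# reported level and loadings in the ranges typical for the English version
# (weaker, partly reverse-keyed EOT items). The corpus composition (number
# of samples, language mix, clinical mix, reporting mix, sample-size
# distribution, censoring threshold) emulates the published evidence base
# for this instrument.
loadings:
  # item: [factor, lambda]
  item01: [DIF, 0.70]
  item02: [DDF, 0.68]
  item03: [DIF, 0.72]
  item04: [DDF, 0.58]
  item05: [EOT, 0.40]
  item06: [DIF, 0.65]
  item07: [DIF, 0.68]
  item08: [EOT, 0.55]
  item09: [DIF, 0.75]
  item10: [EOT, 0.42]
  item11: [DDF, 0.62]
  item12: [DDF, 0.66]
  item13: [DIF, 0.66]
  item14: [DIF, 0.62]
  item15: [EOT, 0.50]
  item16: [EOT, 0.48]
  item17: [DDF, 0.60]
  item18: [EOT, 0.38]
  item19: [EOT, 0.36]
  item20: [EOT, 0.58]
factor_correlations:
  DIF_DDF: 0.77
  DDF_EOT: 0.47
  DIF_EOT: 0.32
# optional residual-correlation overlay among the reverse-keyed items
# (correlated-uniqueness structure); 0 disables it
residual_correlation_negative_keyed: 0.0
corpus:
  k: 88
  n_median: 327
  n_sdlog: 0.8
  n_min: 99
  languages:
    English: 34
    French: 8
    German: 7
    Farsi: 6
    Portuguese: 5
    Japanese: 5
    Turkish: 4
    Spanish: 4
    Korean: 3
    Dutch: 3
    Italian: 2
    Finnish: 2
    Chinese: 2
    Swedish: 1
    Hindi: 1
    Arabic: 1
  clinical_k: 20
  reporting_mix:
    raw_correlations: 3
    efa_pattern: 27
    cfa_pattern: 58
  censor_threshold: 0.40
# additive loading offsets applied to every non-English (translated) group:
# item 5 tends to perform better and item 12 worse in translations
group_perturbations:
  translated:
    item05: 0.14
    item12: -0.11
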