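# Item-to-factor assignments for the TAS-20 measurement-model catalogue.
#
# Items are numbered 1..20 as in the published instrument. DIF/DDF/EOT follow
# the standard scoring key; the PT/IOE sub-facet splits of EOT (models 3b/4)
# and the alternative 3c allocation come from the four-factor literature and
# are configuration, not code: edit here to study alternative allocations.
# The model degrees of freedom computed from these lists are cross-checked
# against the published fit table, which is the decisive structural test.
n_items: 20
negative_keyed: [4, 5, 10, 18, 19]
factors:
  DIF: [1, 3, 6, 7, 9, 13, 14]
  DDF: [2, 4, 11, 12, 17]
  EOT: [5, 8, 10, 15, 16, 18, 19, 20]
  # EOT sub-facets: pragmatic thinking / lack of importance of emotions
  PT:  [5, 8, 15, 20]
  IOE: [10, 16, 18, 19]
  # alternative three-dimensional allocation (model 3c): factor labels are
  # retained although items load on other factors than in the standard key
  EOT_3c: [5, 8, 15, 16, 20]
  IOE_3c: [10, 18, 19]
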