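# Driver-gene -> hallmark map for the melanoma lattice model.
#
# Hallmark tags: p = increased proliferation, q = increased survival,
# r = genetic instability (raised mutation rate), c = decreased antigenicity
# (immune evasion), ct = increased antigenicity.
#
# The assignments below are editable package defaults chosen from the known
# biology of each gene; replace this file (or pass your own via
# read_driver_map()) to use a different hallmark table.
n_genes: 50
drivers:
  - gene: BRAF
    locus: 1
    tags: [p, q, c]
  - gene: NRAS
    locus: 2
    tags: [p]
  - gene: KIT
    locus: 3
    tags: [p]
  - gene: TERT
    locus: 4
    tags: [q]
  - gene: CDKN2A
    locus: 5
    tags: [p]
  - gene: MITF
    locus: 6
    tags: [q]
  - gene: PTEN
    locus: 7
    tags: [q, r]
exclusivity: [BRAF, NRAS, KIT]
motility_gene: BRAF
founder_gene: BRAF
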