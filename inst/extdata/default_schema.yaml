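# Default cell-type schema for merging a MoNuSAC-trained and a
# PanNuke-trained HoVer-Net model. Child nodes are always consistent with
# their parents; cross-model type equality is evaluated at each node's
# match level (default: its depth-1 ancestor).
tree:
  cell:
    epithelial:
      neoplastic epithelial:
      non-neoplastic epithelial:
    inflammatory:
      lymphocyte:
      neutrophil:
      macrophage:
    connective:
    dead:
# match_level overrides are unnecessary here: the depth-1 rule already
# matches lymphocyte/neutrophil/macrophage against inflammatory and both
# PanNuke epithelial subtypes against epithelial.
models:
  monusac:
    labels:
      epithelial: epithelial
      lymphocyte: lymphocyte
      neutrophil: neutrophil
      macrophage: macrophage
  pannuke:
    labels:
      neoplastic epithelial: neoplastic epithelial
      non-neoplastic epithelial: non-neoplastic epithelial
      connective: connective
      inflammatory: inflammatory
      dead: dead
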