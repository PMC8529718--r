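# Example taxonomic assignment rules for the synthetic carpet-shark fixture.
# The family -> node map is an illustration and must be confirmed by the user
# for any real analysis; only the node definitions (MRCA taxon pairs) are
# fixed by the tree.
family_node:
  Orectolobidae: node2
  Brachaeluridae: node2
  Ginglymostomatidae: node3
  Stegostomatidae: node5
  Rhincodontidae: node5
  Hemiscylliidae: node7
genus_node:
  Pseudoginglymostoma: node5
exclude_genera:
  - Pararhincodon
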