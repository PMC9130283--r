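# Mutually exclusive lineage compartments used by the hybrid-artifact rule:
# a phenocluster calling positive markers from two or more distinct
# compartments (e.g. epithelial + hematopoietic) is discarded as a
# segmentation artifact (juxtaposed cells sharing one pseudo-cell ROI).
# Markers absent from every list (MMP7, P-gP, BCRP) are lineage-neutral.
epithelial:     [PanCK, MUC5b, SPD, AQP5, PDPN, NKX2-1, RAGE, HOP, ABCA3]
hematopoietic:  [CD206, PAX5, OPN, CD3, MPO]
mesenchymal:    [COLL1, FGF10, VIM]
vascular:       [aSMA, SM22, DESM, vWF]
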