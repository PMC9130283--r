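# Default MILAN staining design for the mouse lung panel: 24 primary
# antibodies over 11 rounds (3 fluor channels + DAPI per round), plus a
# dedicated blank autofluorescence round (round 0, handled by the pipeline).
# `targets` lists the cell types a marker is a lineage signature for; an empty
# list means the marker is measured (and may be clustered on) but carries no
# lineage information (P-gP, MMP7) or is excluded from classification (BCRP).
# Channel assignments are reconstructed from the secondary-antibody design
# (AF488 = FITC, rhodamine = TRITC, AF647 = FARRED), one fluor per marker per
# round. Catalog numbers / dilutions are bookkeeping metadata only.
name: mouse_lung_milan_24
n_rounds: 11
markers:
  - {short_name: COLL1,   round: 1,  channel: FARRED, host: mo IgG3,    classify: true,
     targets: [stromal]}
  - {short_name: aSMA,    round: 1,  channel: TRITC,  host: mo IgG2a,   classify: true,
     targets: [vasculature, myofibroblast_smc]}
  - {short_name: SM22,    round: 2,  channel: FITC,   host: goat,       classify: true,
     targets: [vasculature, myofibroblast_smc]}
  - {short_name: DESM,    round: 2,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [vasculature, myofibroblast_smc]}
  - {short_name: vWF,     round: 3,  channel: FITC,   host: goat,       classify: true,
     targets: [vasculature]}
  - {short_name: PanCK,   round: 3,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT1, AT2, transitional_AT, bronchial_goblet]}
  - {short_name: MUC5b,   round: 4,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [bronchial_goblet]}
  - {short_name: CD206,   round: 4,  channel: FITC,   host: goat,       classify: true,
     targets: [macrophage]}
  - {short_name: SPD,     round: 5,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT2, transitional_AT]}
  - {short_name: PAX5,    round: 5,  channel: FITC,   host: rb Mab,     classify: true,
     targets: [B_cell]}
  - {short_name: AQP5,    round: 6,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT1, transitional_AT]}
  - {short_name: OPN,     round: 6,  channel: FITC,   host: goat,       classify: true,
     targets: [macrophage, neutrophil]}
  - {short_name: PDPN,    round: 7,  channel: FITC,   host: s.hamster,  classify: true,
     targets: [AT1, transitional_AT]}
  - {short_name: MMP7,    round: 7,  channel: TRITC,  host: rb Mab,     classify: true,
     targets: []}
  - {short_name: NKX2-1,  round: 8,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT2, transitional_AT]}
  - {short_name: CD3,     round: 8,  channel: TRITC,  host: rb poly,    classify: true,
     targets: [T_cell]}
  - {short_name: RAGE,    round: 9,  channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT1, transitional_AT]}
  - {short_name: MPO,     round: 9,  channel: FITC,   host: rb poly,    classify: true,
     targets: [neutrophil]}
  - {short_name: HOP,     round: 10, channel: FARRED, host: mo IgG1,    classify: true,
     targets: [AT1, transitional_AT]}
  - {short_name: ABCA3,   round: 10, channel: TRITC,  host: mo IgG2a,   classify: true,
     targets: [AT2, transitional_AT]}
  - {short_name: FGF10,   round: 10, channel: FITC,   host: goat,       classify: true,
     targets: [stromal]}
  - {short_name: VIM,     round: 11, channel: FITC,   host: mo IgG1,    classify: true,
     targets: [stromal]}
  - {short_name: P-gP,    round: 11, channel: TRITC,  host: rb poly,    classify: true,
     targets: []}
  - {short_name: BCRP,    round: 11, channel: FARRED, host: rat IgG2a,  classify: false,
     targets: []}
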