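# ROI atlas and network classification rules.
#
# Regions are unions of spheres (centre in MNI mm, radius mm, hemisphere tag
# L/R/M). MTG, ANG, IFG, TP, SMA/pre-SMA, dACC and AIFO centres come from the
# group peak tables of the source series; SMG/TPJ, DLPFC, OFC, IPS, FEF
# centres are literature-conventional (no coordinates were published for
# those networks) and are classification conventions of this package.
regions:
  MTG:
    - {centre: [-63, -28, -9], radius: 12, hemisphere: L}
    - {centre: [62, -30, -11], radius: 12, hemisphere: R}
  ANG:
    - {centre: [-54, -55, 30], radius: 12, hemisphere: L}
    - {centre: [57, -55, 36],  radius: 12, hemisphere: R}
  TP:
    - {centre: [-51, 21, -11], radius: 12, hemisphere: L}
    - {centre: [51, 14, -12],  radius: 12, hemisphere: R}
  IFG:
    - {centre: [-47, 27, -9],  radius: 12, hemisphere: L}
    - {centre: [51, 30, -11],  radius: 12, hemisphere: R}
  SMA_preSMA:
    - {centre: [-1, 13, 59],   radius: 12, hemisphere: M}
  dACC:
    - {centre: [0, 28, 28],    radius: 12, hemisphere: M}
  AIFO:
    - {centre: [-38, 18, -9],  radius: 12, hemisphere: L}
    - {centre: [48, 12, -2],   radius: 12, hemisphere: R}
  SMG_TPJ:
    - {centre: [-57, -45, 12], radius: 12, hemisphere: L}
    - {centre: [57, -45, 12],  radius: 12, hemisphere: R}
  DLPFC:
    - {centre: [-42, 36, 28],  radius: 12, hemisphere: L}
    - {centre: [44, 36, 28],   radius: 12, hemisphere: R}
  OFC:
    - {centre: [-34, 48, -8],  radius: 12, hemisphere: L}
    - {centre: [36, 48, -8],   radius: 12, hemisphere: R}
  IPS:
    - {centre: [-26, -58, 52], radius: 12, hemisphere: L}
    - {centre: [26, -58, 52],  radius: 12, hemisphere: R}
  FEF:
    - {centre: [-26, -6, 52],  radius: 12, hemisphere: L}
    - {centre: [26, -6, 52],   radius: 12, hemisphere: R}

# A component fully satisfies a rule when every required region contains at
# least one peak (either hemisphere) and no exclusion region holds a peak
# that dominates (outranks) the best required-region peak. The ANG-vs-SMG/TPJ
# opposition separates the language network from the ventral attention
# network; DLPFC/OFC dominance marks the left fronto-parietal control
# network. Rule priority (tie-break) is the listed order.
rules:
  - network: LANG
    required: [MTG, ANG, IFG]
    exclusion: []
  - network: VAN
    required: [SMG_TPJ, IFG]
    exclusion: [ANG]
  - network: SN
    required: [dACC, SMA_preSMA, AIFO]
    exclusion: []
  - network: DAN
    required: [IPS, FEF]
    exclusion: []
  - network: lFPC
    required: [DLPFC, OFC]
    exclusion: [MTG]
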