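# Synthetic resting-state network templates.
#
# Each node is an isotropic Gaussian blob: [x, y, z] in MNI mm, amplitude,
# sigma in mm. LANG node coordinates are the group peaks of the resting-state
# language network (MTG, ANG, IFG, posterior medial frontal, right
# cerebellum); SN nodes follow the cingulo-opercular peaks of the task
# activation table (dACC, posterior pre-SMA, bilateral anterior
# insula/frontal operculum). VAN, DAN, lFPC, DMN and VIS have no published
# coordinates in the source series; their nodes use literature-conventional
# locations chosen here (TPJ/ventral frontal for VAN, IPS/FEF for DAN,
# DLPFC/anterior OFC for lFPC, PCC/mPFC for DMN, medial occipital for VIS)
# and are simulation inputs, not claims about any patient data.
LANG:
  - {xyz: [-63, -28, -9],  amplitude: 1.0, sigma: 12}   # L mid-posterior MTG
  - {xyz: [-54, -55, 30],  amplitude: 1.0, sigma: 12}   # L angular gyrus
  - {xyz: [-47, 27, -9],   amplitude: 1.0, sigma: 12}   # L IFG (p. orbitalis)
  - {xyz: [-6, 17, 64],    amplitude: 1.0, sigma: 12}   # posterior medial frontal
  - {xyz: [24, -76, -30],  amplitude: 1.0, sigma: 12}   # R cerebellum (crus 1)
VAN:
  - {xyz: [57, -45, 12],   amplitude: 1.0, sigma: 12}   # R supramarginal / TPJ
  - {xyz: [52, 24, -4],    amplitude: 1.0, sigma: 12}   # R IFG / ventral PFC
  - {xyz: [42, 50, 4],     amplitude: 1.0, sigma: 12}   # R ventral middle frontal
SN:
  - {xyz: [0, 28, 28],     amplitude: 1.0, sigma: 12}   # dorsal ACC
  - {xyz: [3, 8, 54],      amplitude: 1.0, sigma: 12}   # posterior pre-SMA
  - {xyz: [-38, 18, -9],   amplitude: 1.0, sigma: 12}   # L anterior insula/operculum
  - {xyz: [48, 12, -2],    amplitude: 1.0, sigma: 12}   # R anterior insula/operculum
DAN:
  - {xyz: [-26, -58, 52],  amplitude: 1.0, sigma: 12}   # L superior IPS
  - {xyz: [26, -58, 52],   amplitude: 1.0, sigma: 12}   # R superior IPS
  - {xyz: [-26, -6, 52],   amplitude: 1.0, sigma: 12}   # L frontal eye field
  - {xyz: [26, -6, 52],    amplitude: 1.0, sigma: 12}   # R frontal eye field
lFPC:
  - {xyz: [-42, 36, 28],   amplitude: 1.0, sigma: 12}   # L DLPFC
  - {xyz: [-34, 48, -8],   amplitude: 1.0, sigma: 12}   # L anterior orbitofrontal
  - {xyz: [-44, -56, 48],  amplitude: 1.0, sigma: 12}   # L superior IPL
DMN:
  - {xyz: [0, -52, 28],    amplitude: 1.0, sigma: 12}   # posterior cingulate/precuneus
  - {xyz: [0, 52, -6],     amplitude: 1.0, sigma: 12}   # medial prefrontal
VIS:
  - {xyz: [-14, -86, 4],   amplitude: 1.0, sigma: 12}   # L medial occipital
  - {xyz: [14, -86, 4],    amplitude: 1.0, sigma: 12}   # R medial occipital
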