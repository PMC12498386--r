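# Rigid explicit water model registry: site geometries and nonbonded
# parameters from the models' original parametrizations.
#
# Geometry conventions (molecular frame): oxygen at the origin, the two
# hydrogens in the xy-plane symmetric about the +x bisector. A massless
# charge site (M) lies on the +x bisector at r_om from the oxygen. Lone-pair
# sites (L) lie in the xz-plane symmetric about the -x bisector at r_ol from
# the oxygen with mutual angle lol_angle_deg.
#
# Units: distances Angstrom, angles degrees, charges elementary charge,
# lj_sigma Angstrom, lj_epsilon kcal/mol, dipole_reference Debye.
tip3p:
  r_oh: 0.9572
  hoh_angle_deg: 104.52
  q_h: 0.417
  q_o: -0.834
  lj_sigma: 3.15061
  lj_epsilon: 0.1521
  dipole_reference: 2.35
tip4p:
  r_oh: 0.9572
  hoh_angle_deg: 104.52
  q_h: 0.52
  q_m: -1.04
  r_om: 0.15
  lj_sigma: 3.15365
  lj_epsilon: 0.155
  dipole_reference: 2.18
tip5p:
  r_oh: 0.9572
  hoh_angle_deg: 104.52
  q_h: 0.241
  q_l: -0.241
  r_ol: 0.70
  lol_angle_deg: 109.47
  lj_sigma: 3.12
  lj_epsilon: 0.16
  dipole_reference: 2.29
spce:
  r_oh: 1.0
  hoh_angle_deg: 109.47
  q_h: 0.4238
  q_o: -0.8476
  lj_sigma: 3.166
  lj_epsilon: 0.1553
  dipole_reference: 2.35
opc:
  r_oh: 0.8724
  hoh_angle_deg: 103.6
  q_h: 0.6791
  q_m: -1.3582
  r_om: 0.1594
  lj_sigma: 3.16655
  lj_epsilon: 0.2128
  dipole_reference: 2.48
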