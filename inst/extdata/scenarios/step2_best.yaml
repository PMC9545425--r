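# Best-supported Step-2 scenario: eight sampled red-knot populations, five
# divergence events and three pulse-admixture events. A Nearctic refugial
# branch (ghost deme "nearctic", unsampled) splits first from the
# Palearctic/Beringian ancestor; the sampled Nearctic branch (rufa) is later
# founded by admixture between that refugial branch and the roselaari branch
# (secondary contact); islandica is recently founded by rufa x canutus
# admixture; piersmai is founded by canutus x rogersi admixture.
#
# Times are generations (6-year generation time for reporting conversions).
# Prior ranges are NON-CANONICAL: they bracket published posterior credible
# intervals where printed, and field-plausible ranges otherwise. Point
# estimates are posterior means where printed; unprinted values (backbone
# split times, r3, per-branch Ne not individually printed) are representative
# choices inside the printed ranges (Ne 4,231-50,616; admixture rates
# 0.3-0.7).
name: step2_best
description: >
  Nearctic-refugium rooting with admixed origins of islandica (rufa x
  canutus), piersmai (rogersi x canutus) and of the sampled Nearctic branch
  (refugial x roselaari).
populations: [rufa, islandica, canutus, piersmai, rogersi1, rogersi2, roselaariW, roselaariE]
ghosts: [nearctic]
ne:
  rufa: N_rufa
  islandica: N_islandica
  canutus: N_canutus
  piersmai: N_piersmai
  rogersi1: N_rogersi1
  rogersi2: N_rogersi2
  roselaariW: N_roselaariW
  roselaariE: N_roselaariE
  nearctic: N_nearctic
sample_sizes:
  rufa: 10
  islandica: 10
  canutus: 10
  piersmai: 10
  rogersi1: 10
  rogersi2: 10
  roselaariW: 10
  roselaariE: 10
missingness: 0.045
events:
  # islandica founded by rufa (fraction r1) and canutus (1 - r1)
  - {type: admix, time: t_isl, target: islandica, source1: rufa, source2: canutus, rate: r1}
  - {type: merge, time: t_rog12, source: rogersi2, dest: rogersi1}
  - {type: size, time: t_rog12, pop: rogersi1, size: Na_rog}
  # piersmai founded by rogersi (fraction r2) and canutus (1 - r2)
  - {type: admix, time: t_pie, target: piersmai, source1: rogersi1, source2: canutus, rate: r2}
  # sampled Nearctic branch founded by roselaari (r3) and the refugial branch
  - {type: admix, time: t_adm_ros, target: rufa, source1: roselaariW, source2: nearctic, rate: r3}
  - {type: merge, time: t_rosWE, source: roselaariE, dest: roselaariW}
  - {type: size, time: t_rosWE, pop: roselaariW, size: Na_ros}
  - {type: merge, time: t_canrog, source: canutus, dest: rogersi1}
  - {type: size, time: t_canrog, pop: rogersi1, size: Na_pal}
  - {type: merge, time: t_ros_split, source: roselaariW, dest: rogersi1}
  - {type: size, time: t_ros_split, pop: rogersi1, size: Na_ber}
  - {type: merge, time: t_root, source: nearctic, dest: rogersi1}
  - {type: size, time: t_root, pop: rogersi1, size: Na_root}
priors:
  t_root: {dist: uniform, min: 2000, max: 10000}
  t_ros_split: {dist: uniform, min: 1400, max: 3000}
  t_canrog: {dist: uniform, min: 1000, max: 2400}
  t_rosWE: {dist: uniform, min: 400, max: 2100}
  t_rog12: {dist: uniform, min: 80, max: 1100}
  t_adm_ros: {dist: uniform, min: 350, max: 1800}
  t_pie: {dist: uniform, min: 500, max: 1800}
  t_isl: {dist: uniform, min: 140, max: 1100}
  r1: {dist: uniform, min: 0.05, max: 0.95}
  r2: {dist: uniform, min: 0.05, max: 0.95}
  r3: {dist: uniform, min: 0.05, max: 0.95}
  N_rufa: {dist: uniform, min: 1000, max: 60000}
  N_islandica: {dist: uniform, min: 1000, max: 60000}
  N_canutus: {dist: uniform, min: 1000, max: 60000}
  N_piersmai: {dist: uniform, min: 1000, max: 60000}
  N_rogersi1: {dist: uniform, min: 1000, max: 60000}
  N_rogersi2: {dist: uniform, min: 1000, max: 60000}
  N_roselaariW: {dist: uniform, min: 1000, max: 60000}
  N_roselaariE: {dist: uniform, min: 1000, max: 60000}
  N_nearctic: {dist: uniform, min: 1000, max: 60000}
  Na_rog: {dist: uniform, min: 1000, max: 60000}
  Na_ros: {dist: uniform, min: 1000, max: 60000}
  Na_pal: {dist: uniform, min: 1000, max: 60000}
  Na_ber: {dist: uniform, min: 1000, max: 60000}
  Na_root: {dist: uniform, min: 1000, max: 60000}
constraints:
  - t_ros_split < t_root
  - t_canrog < t_ros_split
  - t_rosWE < t_ros_split
  - t_adm_ros < t_ros_split
  - t_pie < t_canrog
  - t_isl < t_canrog
  - t_isl < t_adm_ros
  - t_rog12 < t_canrog
point_estimates:
  t_root: 5619.7        # 33,718 ybp at 6 years/generation
  t_ros_split: 2000     # unprinted backbone split; representative
  t_canrog: 1333        # unprinted backbone split; representative
  t_rosWE: 1120.3       # 6,722 ybp
  t_rog12: 471.7        # 2,830 ybp
  t_adm_ros: 1059.3     # 6,356 ybp
  t_pie: 1000           # unprinted; representative (older than t_isl)
  t_isl: 540.3          # 3,242 ybp
  r1: 0.67              # islandica ancestry fraction from rufa
  r2: 0.67              # piersmai ancestry fraction from rogersi
  r3: 0.5               # unprinted; representative
  N_rufa: 4231
  N_islandica: 45000
  N_canutus: 20000
  N_piersmai: 50616
  N_rogersi1: 15000
  N_rogersi2: 5000
  N_roselaariW: 6000
  N_roselaariE: 15000
  N_nearctic: 20000
  Na_rog: 20000
  Na_ros: 20000
  Na_pal: 20000
  Na_ber: 20000
  Na_root: 20000
trios:
  - {target: islandica, source1: rufa, source2: canutus, rate_param: r1}
  - {target: piersmai, source1: rogersi1, source2: canutus, rate_param: r2}
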