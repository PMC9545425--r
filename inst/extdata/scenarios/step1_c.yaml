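# Step-1 scenario c (the Step-1 winner): population topology rooted so that
# the Nearctic branch (rufa/islandica) splits first from the
# Palearctic/Beringian group, with two admixture pulses: a founding of
# piersmai from rogersi x canutus and a founding of the sampled Nearctic
# branch from a Nearctic refugial ghost branch x roselaari.
# Times in generations. Prior ranges are non-canonical (see scenarios
# README).
name: step1_c
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
sample_sizes: {rufa: 10, islandica: 10, canutus: 10, piersmai: 10,
               rogersi1: 10, rogersi2: 10, roselaariW: 10, roselaariE: 10}
missingness: 0.045
events:
  - {type: merge, time: t_isl_split, source: islandica, dest: rufa}
  - {type: merge, time: t_rog12, source: rogersi2, dest: rogersi1}
  - {type: admix, time: t_pie, target: piersmai, source1: rogersi1, source2: canutus, rate: r2}
  - {type: admix, time: t_adm_ner, target: rufa, source1: roselaariW, source2: nearctic, rate: r3}
  - {type: merge, time: t_rosWE, source: roselaariE, dest: roselaariW}
  - {type: merge, time: t_canrog, source: canutus, dest: rogersi1}
  - {type: merge, time: t_ros_split, source: roselaariW, dest: rogersi1}
  - {type: merge, time: t_root, source: nearctic, dest: rogersi1}
priors:
  t_root: {dist: uniform, min: 2000, max: 10000}
  t_ros_split: {dist: uniform, min: 1400, max: 3000}
  t_canrog: {dist: uniform, min: 1000, max: 2400}
  t_rosWE: {dist: uniform, min: 400, max: 2100}
  t_rog12: {dist: uniform, min: 80, max: 1100}
  t_adm_ner: {dist: uniform, min: 350, max: 1800}
  t_pie: {dist: uniform, min: 500, max: 1800}
  t_isl_split: {dist: uniform, min: 140, max: 1100}
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
constraints:
  - t_ros_split < t_root
  - t_canrog < t_ros_split
  - t_rosWE < t_ros_split
  - t_adm_ner < t_ros_split
  - t_pie < t_canrog
  - t_rog12 < t_canrog
  - t_isl_split < t_adm_ner
trios:
  - {target: piersmai, source1: rogersi1, source2: canutus, rate_param: r2}
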