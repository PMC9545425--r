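# Step-1 scenario d: alternative hypothesis for the Palearctic
# relationships — a topology consistent with the NJ tree in which canutus
# and rogersi both have admixed origins (canutus from the Nearctic branch x
# piersmai; rogersi from piersmai x roselaari). No ghost branch.
# Times in generations. Prior ranges are non-canonical (see scenarios
# README).
name: step1_d
populations: [rufa, islandica, canutus, piersmai, rogersi1, rogersi2, roselaariW, roselaariE]
ne:
  rufa: N_rufa
  islandica: N_islandica
  canutus: N_canutus
  piersmai: N_piersmai
  rogersi1: N_rogersi1
  rogersi2: N_rogersi2
  roselaariW: N_roselaariW
  roselaariE: N_roselaariE
sample_sizes: {rufa: 10, islandica: 10, canutus: 10, piersmai: 10,
               rogersi1: 10, rogersi2: 10, roselaariW: 10, roselaariE: 10}
missingness: 0.045
events:
  - {type: merge, time: t_isl_split, source: islandica, dest: rufa}
  - {type: merge, time: t_rog12, source: rogersi2, dest: rogersi1}
  - {type: merge, time: t_rosWE, source: roselaariE, dest: roselaariW}
  - {type: admix, time: t_can, target: canutus, source1: rufa, source2: piersmai, rate: r_c}
  - {type: admix, time: t_rog, target: rogersi1, source1: piersmai, source2: roselaariW, rate: r_r}
  - {type: merge, time: t_ros2, source: roselaariW, dest: piersmai}
  - {type: merge, time: t_root, source: rufa, dest: piersmai}
priors:
  t_root: {dist: uniform, min: 2000, max: 10000}
  t_ros2: {dist: uniform, min: 1400, max: 3000}
  t_rog: {dist: uniform, min: 800, max: 2400}
  t_can: {dist: uniform, min: 500, max: 1800}
  t_rosWE: {dist: uniform, min: 400, max: 2100}
  t_rog12: {dist: uniform, min: 80, max: 750}
  t_isl_split: {dist: uniform, min: 140, max: 1100}
  r_c: {dist: uniform, min: 0.05, max: 0.95}
  r_r: {dist: uniform, min: 0.05, max: 0.95}
  N_rufa: {dist: uniform, min: 1000, max: 60000}
  N_islandica: {dist: uniform, min: 1000, max: 60000}
  N_canutus: {dist: uniform, min: 1000, max: 60000}
  N_piersmai: {dist: uniform, min: 1000, max: 60000}
  N_rogersi1: {dist: uniform, min: 1000, max: 60000}
  N_rogersi2: {dist: uniform, min: 1000, max: 60000}
  N_roselaariW: {dist: uniform, min: 1000, max: 60000}
  N_roselaariE: {dist: uniform, min: 1000, max: 60000}
constraints:
  - t_ros2 < t_root
  - t_rog < t_ros2
  - t_rosWE < t_ros2
  - t_rog12 < t_rog
  - t_can < t_root
  - t_isl_split < t_can
trios:
  - {target: canutus, source1: rufa, source2: piersmai, rate_param: r_c}
  - {target: rogersi1, source1: piersmai, source2: roselaariW, rate_param: r_r}
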