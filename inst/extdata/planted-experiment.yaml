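# Example experiment configuration for the pipeline CLI:
#   Rscript inst/cli/graspdecode.R run --config planted-experiment.yaml \
#           --seed 1 --out report/
# Uses the shipped "planted" scenario (synthetic: action-type pattern in all
# brain ROIs, grasp-type pattern except SPOC / right hAIP, silent control).
design:
  n_runs: 4
  tr: 3.0
  volumes_per_run: 117
  trials_per_condition: 45
  miniblock_size: 5
  isi_range: [3, 8]
  isi_mean_target: 4.9
rois:
  preset: planted
  n_voxels: 100
hrf:
  peak_delay: 6
  undershoot_delay: 16
  ratio: 6
noise:
  white_sd: 1.0
  ar1: 0.3
  drift_amplitude: 1.0
  drift_period: 128
n_subjects: 16
classifications: [size_grasp, size_reach, grasp_type, congruence,
                  pg_vs_reach, whg_vs_reach]
stats:
  q: 0.05
  include_control_in_family: true
subject_pattern_sd: 0.3
seed: 1
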