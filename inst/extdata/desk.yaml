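# Desk-scale preset: coarse synthetic phantom (~2300 nodes) with a
# cylindrical lumpectomy, run to the 90-day horizon. Biology, materials and
# schedule fall back to the packaged defaults (default_params.yaml).
# Healing is simulated in the fixed supine frame without gravity: the
# contraction metric is the normalised wound-volume ratio, to which the
# (constant-in-time) gravity preload contributes only a fixed offset.

phantom:
  breast_radius: 0.06        # m
  slab_depth: 0.02           # m
  target_edge_length: 0.010  # m
  fibro_fraction: 0.25
  seed: 1

resection:
  axis_point: [0.018, 0.0, 0.0]   # on the chest wall, lower-outer quadrant
  axis_direction: [0.0, 1.0, 0.0] # perpendicular to the chest wall
  radius: 0.02                    # m

gravity:
  pose: none
  magnitude: 9.81

biology: {}
materials: {}
schedule:
  dt_bio: 5000      # s; the coarse desk mesh admits a much larger stable
                    # step than the fine-mesh 17.28 s reference
  dt_mech_days: 6
  t_end_days: 90
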