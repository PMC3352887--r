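# Example flytrackr experiment configuration.
# Thresholds are FBL fractions (dimensionless), never raw pixels, so the
# same config transfers between camera setups.
schedule:
  lights_on_s: 0        # experiment second of the first lights-on (ZT0)
  photoperiod_min: 720  # 12 h light
  cycle_min: 1440       # 24 h cycle
thresholds:
  min_fraction: 0.5     # minimum movement threshold (50% FBL)
  max_fraction: 1.5     # artifact cutoff (150% FBL)
tube_length_mm: 65
jobs:
  - fly_id: fly1
    roi: {xmin: 10, xmax: 660, ymin: 10, ymax: 50}
    fbl_px: 10
    food_end: high      # food plug at the high-coordinate end of the axis
    contrast_threshold: 60
    min_area: 5
    max_area: 400
  - fly_id: fly2
    roi: {xmin: 10, xmax: 660, ymin: 60, ymax: 100}
    fbl_px: 10
    food_end: high
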