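tank:
  length_x_cm: 43.0
  width_y_cm: 8.0
  height_z_cm: 14.0
dt_s: 0.1
cameras:
  top:
    image_w_px: 1920
    image_h_px: 1080
    roi: [160, 340, 1760, 740]
    flip_v: false
  side:
    image_w_px: 1920
    image_h_px: 1080
    roi: [160, 140, 1760, 940]
    flip_v: true
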