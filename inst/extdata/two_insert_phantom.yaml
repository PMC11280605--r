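# Example phantom spec: a water disk with two CEST inserts at 300 Hz.
# Coordinates are 0-based (row, col) pixel indices, row-major.
shape: [48, 48]
grid:
  offsets_hz: [-1000, -900, -800, -700, -600, -500, -400, -300, -200, -100,
               0, 100, 200, 300, 400, 500, 600, 700, 800, 900, 1000]
  ref_index: 1
  water_offset_hz: 0
  pool_offsets_hz: [300]
phase_coef: [0.1, 0.4, -0.3, 0.2, 0.0, 0.0]
compartments:
  - name: air
    geometry: {type: background}
    s0: 0
    zspec: {a: 0, gamma: 10000}
  - name: water
    geometry: {type: disk, center: [23.5, 23.5], radius: 20}
    s0: 1.0
    zspec: {a: 27000, gamma: 30000, model: LG}
  - name: insert_weak
    geometry: {type: disk, center: [23.5, 14], radius: 5}
    s0: 1.0
    zspec:
      a: 27000
      gamma: 30000
      model: LG
      pools: {center_hz: [300], b: [0.05], sigma: [90]}
  - name: insert_strong
    geometry: {type: disk, center: [23.5, 33], radius: 5}
    s0: 1.0
    zspec:
      a: 27000
      gamma: 30000
      model: LG
      pools: {center_hz: [300], b: [0.15], sigma: [90]}
rois:
  insert_weak: {type: disk, center: [23.5, 14], radius: 3.5}
  insert_strong: {type: disk, center: [23.5, 33], radius: 3.5}
  background: {type: rectangle, corner: [1, 1], size: [6, 6]}
background_roi: background
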