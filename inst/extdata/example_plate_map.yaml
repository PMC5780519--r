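# Example plate map: a small pH screen with SYPRO Orange, triplicates + blank.
groups:
  - condition: "pH 6.0"
    wells: [A1, A2, A3]
    dye: {kind: SYPRO, f_native: 100, f_unfolded: 1000, background: 50, decay_rate: 20}
    unfolding: {tm: [46], slope_factor: 2}
  - condition: "pH 7.0"
    wells: [B1, B2, B3]
    dye: {kind: SYPRO, f_native: 100, f_unfolded: 1000, background: 50, decay_rate: 20}
    unfolding: {tm: [50], slope_factor: 2}
  - condition: "pH 8.0"
    wells: [C1, C2, C3]
    dye: {kind: SYPRO, f_native: 100, f_unfolded: 1000, background: 50, decay_rate: 20}
    unfolding: {tm: [48.5], slope_factor: 2}
  - condition: "blank"
    wells: [H10, H11, H12]
    blank: true
    dye: {kind: SYPRO, background: 50}
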