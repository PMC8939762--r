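# Material properties used in treatment-pressure simulation, 20.7 MHz.
# gel uses water values (acoustically near-identical); water is the
# lossless variant for diffraction oracles.
version: 1
media:
  tumor:
    density_kg_m3: 1060
    sound_speed_m_s: 1521
    attenuation_np_mm: 0.321
  skin:
    density_kg_m3: 1060
    sound_speed_m_s: 1558
    attenuation_np_mm: 1.091
  gel:
    density_kg_m3: 1000
    sound_speed_m_s: 1480
    attenuation_np_mm: 0.110
  water:
    density_kg_m3: 1000
    sound_speed_m_s: 1480
    attenuation_np_mm: 0.0
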