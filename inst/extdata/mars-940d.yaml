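# Mars reference mission: 400 days total transit plus 540 days on the
# surface, near average solar minimum. The surface attenuation factor is a
# single multiplicative stand-in for the Mars atmosphere (non-physical knob).
mission:
  dose_rate_mGy_day: 0.4
  solar_condition: average solar minimum
  shield_label: 20 g/cm^2 aluminum
  segments:
    - label: transit
      duration_days: 400
      attenuation: 1.0
    - label: mars surface
      duration_days: 540
      attenuation: 0.45
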