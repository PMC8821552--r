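# Annual deep-space GCR exposure near average solar minimum.
# The flux is the package's synthetic GCR stand-in scaled to the stated
# absorbed-dose rate; it is labelled "behind 20 g/cm^2 aluminum" by
# construction, not by transport.
mission:
  dose_rate_mGy_day: 0.4
  solar_condition: average solar minimum
  shield_label: 20 g/cm^2 aluminum
  segments:
    - label: deep space
      duration_days: 365
      attenuation: 1.0
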