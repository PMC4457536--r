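# repetitive stimulation: five 0.5 ms / 1 V cathodic pulses, 0.5 ms gaps
type: burst
n_pulses: 5
isi_ms: 0.5
pulse:
  type: monophasic
  amplitude_V: 1
  width_ms: 0.5
  polarity: cathodic
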