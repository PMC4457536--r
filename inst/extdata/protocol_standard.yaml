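# the standard stimulation pulse: monophasic cathodic, 1 V, 1 ms
type: monophasic
amplitude_V: 1
width_ms: 1
polarity: cathodic
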