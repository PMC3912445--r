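unit: cm
l0: 10
l_max: 35.4
steps: 8
k: 0.3
survival: 0.8
abundance: 1000000
condition_factor: 0.0104
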