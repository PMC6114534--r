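name: harbaum
grades: [1, 2, 3, 4]
lower_bounds: [0, 5, 17, 20]
shared_endpoints: [5, 17, 20]
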