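{"version":1,"table":[{"N":100,"L":10,"penalty_scale":0.5},{"N":300,"L":10,"penalty_scale":0.5},{"N":1000,"L":10,"penalty_scale":0.5}]}
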