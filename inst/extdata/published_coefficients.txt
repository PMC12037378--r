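format_version = 1
short.beta_lifespan = -0.05629
short.beta_hba1c = 1.127
short.intercept = 3.1779999999999999
short.multiple_R = 0.73599999999999999
mid.beta_lifespan = -0.0047720000000000002
mid.beta_hba1c = 0.75690000000000002
mid.intercept = 2.3940000000000001
mid.multiple_R = 0.73440000000000005
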