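region,age_band,count
BR,10-19,5e+05
BR,20-29,1588449
BR,30-39,848754
BR,40-49,80000
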