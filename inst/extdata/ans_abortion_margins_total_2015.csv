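region,age_band,count
BR,10-19,669
BR,20-29,6696
BR,30-39,11181
BR,40-49,2210
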