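region,age_band,count
BR,10-19,314
BR,20-29,3287
BR,30-39,5188
BR,40-49,1011
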