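region,age_band,count
BR,10-19,16284480
BR,20-29,16995533
BR,30-39,16826200
BR,40-49,13762740
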