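icd9,phecode,exclude_range_lo,exclude_range_hi
001.0,008,,
427.31,427.2,427,427.99
427.9,427.5,,
250.00,250.2,249,250.99
585.9,585.3,,
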