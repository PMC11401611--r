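"admission_id","icd9"
"a1","001.0"
"a2","427.31"
"b1","427.31"
"b2","427.31"
"c1","427.31"
"d1","001.0"
"d2","001.0"
"e1","001.0"
"e2","427.9"
"f1","427.31"
"f2","001.0"
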