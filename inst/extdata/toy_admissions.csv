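"patient_id","admission_id","admit_order"
"A","a1",1
"A","a2",2
"B","b1",1
"B","b2",2
"C","c1",1
"D","d1",1
"D","d2",2
"E","e1",1
"E","e2",2
"F","f1",1
"F","f2",2
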