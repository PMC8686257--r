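"Case ID","Activity","Order","Is Emergency"
"1","rp","1","False"
"1","rj","2","False"
"1","vp","3","False"
"1","uj","4","False"
"1","op","5","False"
"1","uj","6","False"
"2","rp","1","True"
"2","rj","2","True"
"2","op","3","True"
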