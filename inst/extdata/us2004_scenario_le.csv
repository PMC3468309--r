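"scenario","female","male"
"reference","80.2","75.1"
"s3","74.9","70.1"
"s4","79.6","73.9"
"s5","81.1","76.4"
"s6","82.3","78"
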