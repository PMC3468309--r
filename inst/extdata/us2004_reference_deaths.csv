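"cause","sex","deaths"
"Ischemic heart diseases","female","219"
"Cancer of trachea, bronchus, and lung","female","70"
"Chronic lower respiratory diseases","female","65"
"All other causes","female","868"
"Ischemic heart diseases","male","236"
"Cancer of trachea, bronchus, and lung","male","92"
"Chronic lower respiratory diseases","male","61"
"All other causes","male","804"
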