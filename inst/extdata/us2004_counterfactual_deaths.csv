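"cause","sex","deaths"
"Ischemic heart diseases","female","194"
"Cancer of trachea, bronchus, and lung","female","21"
"Chronic lower respiratory diseases","female","18"
"All other causes","female","808"
"Ischemic heart diseases","male","195"
"Cancer of trachea, bronchus, and lung","male","26"
"Chronic lower respiratory diseases","male","21"
"All other causes","male","712"
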