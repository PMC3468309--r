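"sex","parameter","age_lo","age_hi","value"
"female","cumulative_initiation","","","0.35"
"female","initiation_start_age","","","12"
"female","initiation_end_age","","","24"
"female","cessation_hazard_per_y","15","28","0.042"
"female","cessation_hazard_per_y","28","33","0.031"
"female","cessation_hazard_per_y","33","48","0.025"
"female","cessation_hazard_per_y","48","","0.045"
"male","cumulative_initiation","","","0.39"
"male","initiation_start_age","","","12"
"male","initiation_end_age","","","24"
"male","cessation_hazard_per_y","15","28","0.04"
"male","cessation_hazard_per_y","28","33","0.028"
"male","cessation_hazard_per_y","33","48","0.021"
"male","cessation_hazard_per_y","48","","0.06"
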