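measure,numerator,denominator,printed_percent
falls_overall,26480,58516,45
falls_female,13080,25137,52
struck_overall,20845,58516,36
assault_overall,4359,58516,7
sports_male,9804,33379,29
mvc_overall,5808,58516,10
unmatched,4100,239103,1.7
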