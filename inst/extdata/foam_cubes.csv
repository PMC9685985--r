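sample,modulus,spread,printed_infill_percent
OBS,9.06,0.41,7
SYN,33.67,7.12,12
OB,35.6,12.07,12
SAW,155,NA,27
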