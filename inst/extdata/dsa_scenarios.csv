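label,arm,p_lco,source_note
LCO 18%,intervention,0.18,levosimendan CABG trial arm
LCO 6%,intervention,0.06,restrictive LCO definition
LCO 35%,control,0.35,broad LCO definition
LCO 25%,control,0.25,levosimendan CABG trial placebo
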