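"term","code"
"liver","LIVER"
"lung","LUNG"
"lymph node","LYMPH NODE"
"brain","BRAIN"
"kidney","KIDNEY"
"bone","BONE"
"adrenal gland","ADRENAL GLAND"
"pleura","PLEURA"
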