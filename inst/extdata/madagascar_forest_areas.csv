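scope,year,area_ha
national,2005,9700000
national,2020,8100000
mnp,2005,1200000
mnp,2020,1100000
cfm,2005,487900
cfm,2020,385700
cfm,2008,475333
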