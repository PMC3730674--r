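metabolite_id	max_uptake
sucrose[e]	1.5
ammonium[e]	1000
nitrate[e]	1000
phosphate[e]	1000
sulfate[e]	1000
citrate[e]	1000
biotin[e]	1000
Ca2+[e]	1000
Mg2+[e]	1000
K+[e]	1000
Na+[e]	1000
Cl-[e]	1000
Fe2+[e]	1000
Zn2+[e]	1000
Mn2+[e]	1000
Cu2+[e]	1000
Mo[e]	1000
H2O[e]	1000
oxygen[e]	1000
proton[e]	1000
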