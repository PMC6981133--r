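cell_group_name	cnv_name	state	chr	start	end
s1	chr3q-loss	2	chr3	99000001	198000000
s2	chr3q-loss	2	chr3	99000001	198000000
s2	chr3p-loss	1	chr3	1	90000000
s1	chrM-gain	5	chrM	1	16569
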