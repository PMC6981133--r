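cell_group_name	cell
s0	cell_001
s0	cell_002
s0	cell_003
s0	cell_004
s0	cell_005
s0	cell_006
s0	cell_007
s0	cell_008
s0	cell_009
s0	cell_010
s0	cell_011
s0	cell_012
s0	cell_013
s0	cell_014
s0	cell_015
s0	cell_016
s0	cell_017
s0	cell_018
s0	cell_019
s0	cell_020
s0	cell_021
s0	cell_022
s0	cell_023
s0	cell_024
s0	cell_025
s0	cell_026
s0	cell_027
s0	cell_028
s0	cell_029
s0	cell_030
s0	cell_031
s0	cell_032
s0	cell_033
s0	cell_034
s0	cell_035
s0	cell_036
s0	cell_037
s0	cell_038
s0	cell_039
s0	cell_040
s0	cell_041
s0	cell_042
s0	cell_043
s0	cell_044
s0	cell_045
s0	cell_046
s0	cell_047
s0	cell_048
s0	cell_049
s0	cell_050
s0	cell_051
s0	cell_052
s0	cell_053
s0	cell_054
s0	cell_055
s0	cell_056
s0	cell_057
s0	cell_058
s0	cell_059
s0	cell_060
s0	cell_061
s0	cell_062
s0	cell_063
s0	cell_064
s0	cell_065
s0	cell_066
s0	cell_067
s0	cell_068
s0	cell_069
s0	cell_070
s0	cell_071
s0	cell_072
s0	cell_073
s0	cell_074
s0	cell_075
s0	cell_076
s0	cell_077
s1	cell_078
s1	cell_079
s1	cell_080
s1	cell_081
s1	cell_082
s1	cell_083
s1	cell_084
s1	cell_085
s1	cell_086
s1	cell_087
s1	cell_088
s1	cell_089
s1	cell_090
s1	cell_091
s1	cell_092
s1	cell_093
s1	cell_094
s2	cell_095
s2	cell_096
s2	cell_097
s2	cell_098
s2	cell_099
s2	cell_100
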