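# synthetic RSN membership fixture (not atlas-derived)
# each network sits inside one structural community of the synthetic connectome
# network region_index_0based
DMN 0
DMN 1
DMN 2
DMN 3
DMN 4
DMN 5
DMN 6
DMN 7
DMN 8
DMN 9
DMN 10
DMN 11
DMN 12
DMN 13
EXEC 18
EXEC 19
EXEC 20
EXEC 21
EXEC 22
EXEC 23
EXEC 24
EXEC 25
EXEC 26
EXEC 27
EXEC 28
EXEC 29
MN 36
MN 37
MN 38
MN 39
MN 40
MN 41
MN 42
MN 43
MN 44
MN 45
SN 54
SN 55
SN 56
SN 57
SN 58
SN 59
SN 60
SN 61
SN 62
SN 63
VN 72
VN 73
VN 74
VN 75
VN 76
VN 77
VN 78
VN 79
VN 80
VN 81
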