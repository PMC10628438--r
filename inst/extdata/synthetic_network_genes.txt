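NETG01
NETG02
NETG03
NETG04
NETG05
NETG06
NETG07
NETG08
NETG09
NETG10
NETG11
NETG12
NETG13
NETG14
NETG15
NETG16
NETG17
NETG18
NETG19
NETG20
NETG21
NETG22
NETG23
NETG24
NETG25
NETG26
NETG27
NETG28
NETG29
NETG30
NETG31
NETG32
NETG33
NETG34
NETG35
NETG36
NETG37
NETG38
NETG39
NETG40
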