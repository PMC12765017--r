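TC22
TC67
TC538
TC627
TC640
TC902
TC1020
TC1088
TC1123
TC1164
TC1218
TC1241
TC1473
TC1593
TC1601
TC1744
TC1936
TC1979
TC2011
TC2089
TC2110
TC2288
TC2289
TC2402
TCS25
TCS26
TCS27
TCS28
TCS29
TCS30
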