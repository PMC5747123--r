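# STOCKHOLM 1.0
synthetic_m01 GCGUUCUGUUGACGAGAUCCAGUAAUCGACGGUUUGUCGCGUGGUGACAUUGUACUUACUGGACUGCGCA
synthetic_m02 GUUUAAUGCUGCCGAGAACCAGUCCUCGUCGGUUUGUCGCGUGGUGACAUUGAACGGACUGGUCGGAGCA
synthetic_m03 GUUUACUGCCGCCGAGAACCAGUAUUCGUCGCAUUGUCGCGUAGUGACAGUGAACAUACUGGUUUGAGCA
synthetic_m04 GUUUACUGCUGCCGAGAAGCAGCCCUCUUCGCUUUGUUGCGUCGUGACAGUGAACGGGCUGCUCAGAGCA
#=GC SS_cons  (((..............((((((((...((((..((((((...))))))))))..))))))))...))).
//
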