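nucleotide	templates	sequenceStatus
CASSLGQGAETQYF-nt-001	120	In
CASSPTGELFF-nt-002	44	In
CASRRDSYEQYF-nt-003	9	In
CASSFRDRVNTEAFF-nt-004	2	Out
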