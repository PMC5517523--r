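Drop real PDB coordinate files here to run accession-backed checks.
In particular, `1nui.pdb` (T7 DNA primase; distributed by the Protein Data
Bank, not with this package) enables the test verifying the ~7.5 A
separation of the two active-site metal cofactors within one protomer.
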