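pattern	spectral_class	note
Karlodinium micrum	BPR	spectroscopic evidence shows these dinoflagellate PRs are blue-absorbing despite a green-type tuning residue annotation
Ceratium fusus	BPR	spectroscopic evidence shows these dinoflagellate PRs are blue-absorbing despite a green-type tuning residue annotation
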