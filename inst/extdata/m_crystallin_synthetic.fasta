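>m_crystallin_synthetic | 85-residue synthetic stand-in sequence (not the deposited NP_617429 sequence); residue identities at positions named in published work are honored (M1, A2, ..., Q84, I85; three prolines)
MANAEVTVYEHDGFPEKSGDATSDQPGAGENLTDKEGSEKVKLGTLKEYE
YINYGDRVWDLGKGEYESVESAGIPDNSISSFRQI
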