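# Synthetic 32-channel, six-region map for the surrogate EEG examples.
# This is a 10-20-style convenience assignment, NOT any study's montage.
F:  [Fp1, Fp2, F3, F4, Fz, AFz]
C:  [FC1, FC2, C3, C4, Cz, CPz]
P:  [P3, P4, Pz, CP1, CP2, POz]
O:  [O1, O2, Oz, Iz]
LT: [F7, T7, TP7, P7, FT7]
RT: [F8, T8, TP8, P8, FT8]
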