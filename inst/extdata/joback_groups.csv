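group,ring,dTb,dTc,dPc,n_atoms
CH3,0,23.58,0.0141,-0.0012,4
CH2,0,22.88,0.0189,0.0000,3
CH,0,21.74,0.0164,0.0020,2
C,0,18.25,0.0067,0.0043,1
=CH2,0,18.18,0.0113,-0.0028,3
=CH,0,24.96,0.0129,-0.0006,2
=C,0,24.14,0.0117,0.0011,1
=C=,0,26.15,0.0026,0.0028,1
ring-CH2,1,27.15,0.0100,0.0025,3
ring-CH,1,21.78,0.0122,0.0004,2
ring-C,1,21.32,0.0042,0.0061,1
ring=CH,1,26.73,0.0082,0.0011,2
ring=C,1,31.01,0.0143,0.0008,1
OH-alcohol,0,92.88,0.0741,0.0112,2
OH-phenol,0,76.34,0.0240,0.0184,2
O-ether,0,22.42,0.0168,0.0015,1
ring-O,1,31.22,0.0098,0.0048,1
C=O-ketone,0,76.75,0.0380,0.0031,2
ring-C=O,1,94.97,0.0284,0.0028,2
CHO-aldehyde,0,72.24,0.0379,0.0030,3
COOH,0,169.09,0.0791,0.0077,4
COO-ester,0,81.10,0.0481,0.0005,3
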