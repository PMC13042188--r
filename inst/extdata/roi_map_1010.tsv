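channel	roi
Fp1	mfrontal
Fp2	mfrontal
AF3	mfrontal
AF4	mfrontal
F1	mfrontal
Fz	mfrontal
F2	mfrontal
FC1	mfrontal
FCz	mfrontal
FC2	mfrontal
AF7	lfrontal
AF8	lfrontal
F7	lfrontal
F5	lfrontal
F3	lfrontal
F4	lfrontal
F6	lfrontal
F8	lfrontal
FC5	lfrontal
FC3	lfrontal
FC4	lfrontal
FC6	lfrontal
C1	mcentral
Cz	mcentral
C2	mcentral
C5	lcentral
C3	lcentral
C4	lcentral
C6	lcentral
CP1	mparietal
CPz	mparietal
CP2	mparietal
P1	mparietal
Pz	mparietal
P2	mparietal
CP5	lparietal
CP3	lparietal
CP4	lparietal
CP6	lparietal
P5	lparietal
P3	lparietal
P4	lparietal
P6	lparietal
PO7	occipital
PO3	occipital
POz	occipital
PO4	occipital
PO8	occipital
O1	occipital
O2	occipital
FT7	temporal
FT8	temporal
T7	temporal
T8	temporal
TP7	temporal
TP8	temporal
P7	temporal
P8	temporal
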