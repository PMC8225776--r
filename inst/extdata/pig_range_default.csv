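unit,status
POL-1,nonnative
POL-2,nonnative
POL-3,nonnative
MIC-1,nonnative
MIC-2,nonnative
MIC-3,nonnative
GAL-1,nonnative
GAL-2,nonnative
GAL-3,nonnative
NZL-1,nonnative
NZL-2,nonnative
NZL-3,nonnative
CAR-1,nonnative
CAR-2,nonnative
CAR-3,nonnative
MDG-1,nonnative
MDG-2,nonnative
MDG-3,nonnative
IOI-1,nonnative
IOI-2,nonnative
IOI-3,potential
ATL-1,nonnative
ATL-2,nonnative
ATL-3,absent
EUR-1,native
EUR-2,native
EUR-3,native
NAM-1,nonnative
NAM-2,nonnative
NAM-3,nonnative
CAM-1,nonnative
CAM-2,nonnative
CAM-3,absent
SAM-1,nonnative
SAM-2,nonnative
SAM-3,nonnative
AFR-1,native
AFR-2,potential
AFR-3,absent
ASI-1,native
ASI-2,native
ASI-3,native
SEA-1,native
SEA-2,native
SEA-3,native
MDE-1,native
MDE-2,native
MDE-3,native
AUS-1,nonnative
AUS-2,nonnative
AUS-3,nonnative
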