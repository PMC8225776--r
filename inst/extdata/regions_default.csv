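unit,region,system
POL-1,Polynesia,island
POL-2,Polynesia,island
POL-3,Polynesia,island
MIC-1,Micronesia/Melanesia,island
MIC-2,Micronesia/Melanesia,island
MIC-3,Micronesia/Melanesia,island
GAL-1,Galapagos,island
GAL-2,Galapagos,island
GAL-3,Galapagos,island
NZL-1,New Zealand,island
NZL-2,New Zealand,island
NZL-3,New Zealand,island
CAR-1,Caribbean,island
CAR-2,Caribbean,island
CAR-3,Caribbean,island
MDG-1,Madagascar,island
MDG-2,Madagascar,island
MDG-3,Madagascar,island
IOI-1,Indian Ocean Islands,island
IOI-2,Indian Ocean Islands,island
IOI-3,Indian Ocean Islands,island
ATL-1,Atlantic Islands,island
ATL-2,Atlantic Islands,island
ATL-3,Atlantic Islands,island
EUR-1,Europe,continental
EUR-2,Europe,continental
EUR-3,Europe,continental
NAM-1,North America,continental
NAM-2,North America,continental
NAM-3,North America,continental
CAM-1,Central America,continental
CAM-2,Central America,continental
CAM-3,Central America,continental
SAM-1,South America,continental
SAM-2,South America,continental
SAM-3,South America,continental
AFR-1,Africa,continental
AFR-2,Africa,continental
AFR-3,Africa,continental
ASI-1,Mainland Asia,continental
ASI-2,Mainland Asia,continental
ASI-3,Mainland Asia,continental
SEA-1,Southeast Asia,continental
SEA-2,Southeast Asia,continental
SEA-3,Southeast Asia,continental
MDE-1,Middle East,continental
MDE-2,Middle East,continental
MDE-3,Middle East,continental
AUS-1,Australia,continental
AUS-2,Australia,continental
AUS-3,Australia,continental
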