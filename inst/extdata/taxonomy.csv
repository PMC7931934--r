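code,full_name,high_level,aggregated3,aggregated4,aggregated2
CFP,Coastal fish pond,Agriculture,O,O,nonP
CPL,Rubber plantation,Agriculture,P,P,P
DCL,Dry cultivated land,Agriculture,O,O,nonP
DIF,Disturbed upland forest,Disturbed forest,F,F,nonP
DIM,Disturbed mangrove,Disturbed forest,O,O,nonP
DSF,Disturbed swamp forest,Disturbed forest,O,O,nonP
GRS,Upland grassland,Bare soil,O,B,nonP
MIN,Mining,Mining,O,O,nonP
MTC,Mixed tree crops,Agriculture,O,O,nonP
OPL,Oil palm plantation,Oil palm,P,P,P
RCF,Rice fields,Agriculture,O,O,nonP
SCH,Upland shrub land,Bare soil,O,B,nonP
SET,Settlements,Built-up,O,O,nonP
SGR,Swamp grassland,Bare soil,O,B,nonP
SSH,Swamp shrub land,Bare soil,O,B,nonP
TPL,Timber plantation,Timber plantation,P,P,P
UDF,Undisturbed upland forest,Undisturbed forest,F,F,nonP
USF,Undisturbed swamp forest,Undisturbed forest,F,F,nonP
WAB,Water bodies,Water body,O,O,nonP
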