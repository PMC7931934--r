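code,pixels_2000,pixels_2005,pixels_2009,area_2000,area_2005,area_2009
CFP,5120,5159,6324,1.28,1.29,1.58
CPL,18398,19813,19741,4.60,4.95,4.94
DCL,44640,57555,86230,11.16,14.39,21.56
DIF,413561,404786,386326,103.39,101.20,96.58
DIM,6731,6731,6500,1.68,1.68,1.63
DSF,81790,83001,66836,20.45,20.75,16.71
GRS,14772,12026,12273,3.69,3.01,3.07
MIN,1249,2308,4168,0.31,0.58,1.04
MTC,6944,7657,7995,1.74,1.91,2.00
OPL,27948,42572,101806,6.99,10.64,25.45
RCF,28697,29416,30419,7.17,7.35,7.60
SCH,288002,294930,258922,72.00,73.73,64.73
SET,2776,2839,2840,0.69,0.71,0.71
SGR,16713,13887,13525,4.18,3.47,33.8
SSH,98669,103509,108240,24.67,25.88,27.06
TPL,12008,12531,12117,3.00,3.13,3.03
UDF,136217,115656,97007,34.05,28.91,24.25
USF,88069,77928,71035,22.02,19.48,17.76
WAB,19808,19808,19808,4.95,4.95,4.95
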