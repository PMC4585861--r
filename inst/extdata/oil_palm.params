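# Oil palm (Elaeis guineensis) ecoclimatic parameter set.
# Temperatures in degC; soil moisture as fraction of bucket capacity;
# rates per week, signed as printed (cold/dry rates negative).

DV0 = 19
DV1 = 24
DV2 = 28
DV3 = 36

SM0 = 0.4
SM1 = 0.6
SM2 = 1.6
SM3 = 2

TTCS = 15
THCS = -0.005
DTCS = 20
DHCS = -0.0005

TTHS = 36
THHS = 0.001

SMDS = 0.4
HDS = -0.007

SMWS = 2
HWS = 0.0023

PDD = 1500

# Hydrology (not part of the published table): single-bucket capacity in mm
# and bulk evapotranspiration coefficient, calibrated so an ideal tropical
# cell (26 degC, RH 80%, 2250 mm/yr) is in moisture balance.
soil_capacity = 100
k_et = 1.18464697520139
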