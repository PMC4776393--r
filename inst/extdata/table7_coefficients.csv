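term,estimate,se,t,p
(Intercept),12.070,4.446,2.715,0.007
Number_Day2,0.817,0.232,3.522,0.000
TCV_Day2,-1.572,0.547,-2.875,0.004
Fragmentation_Day2,-12.250,6.392,-1.917,0.055
Age_male,-0.311,0.134,-2.328,0.020
Number_Day3,-2.697,0.853,-3.164,0.002
Number_Day2:COD_Day3,-0.412,0.161,-2.549,0.011
TCV_Day2*Age_male,0.045,0.016,2.806,0.005
COD_Day2:Age_male,-0.065,0.026,-2.457,0.014
Fragmentation_Day2*Age_male,0.327,0.190,1.722,0.085
COD_Day2:Number_Day3,1.434,0.637,2.249,0.024
Parity_Day2:Number_Day3,0.730,0.225,3.246,0.001
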