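feature,channel,index,tp,tn,fp,fn,sensitivity,specificity,accuracy,precision
RMSH,horizontal,0,1,36.78,0,1.8841,34.72,100,93.73,100
AMPH,horizontal,1,1,83.5,0.36,3.423,22.60,99.57,95.42,73.52
VarianceH,horizontal,2,1,76.66,1.22,2.30405,30.26,98.43,95.43,45.04
AverageH,horizontal,3,1,79.72,0.051,1.966,33.78,99.93,97.35,95.14
MedianH,horizontal,4,1,79.39,1.151,0.8329,54.64,98.57,97.38,39.84
CovarianceH,horizontal,5,1,16.05,2.5,0.6645,60.24,86.52,80.41,28.57
MaxH,horizontal,6,1,76.30,2.93,0.1949,83.68,96.30,95.87,25.44
PspectrumH,horizontal,7,1,80.36,0.0062,1.09084,47.84,99.99,98.45,34.12
PowerH,horizontal,8,1,82.80,1.937,0.0296,98.03,97.72,97.55,34.12
RMSV,vertical,9,1,81.87,0.3183,0.9022,52.63,99.62,98.37,45.87
AMPV,vertical,10,1,75.76,0.103,2.7607,26.59,99.86,96.14,90.66
VarianceV,vertical,11,1,77.28,0.95497,1.65257,37.73,98.78,96.54,51.28
AverageV,vertical,12,1,82.59,0.7812,1.166,46.16,99.06,97.55,56.14
MedianV,vertical,13,1,79.43,0.0759,0.468,68.11,99.90,97.26,34.55
CovarianceV,vertical,14,1,77.77,1.89397,0.71257,58.47,97.62,96.57,34.60
MaxV,vertical,15,1,73.95,2.9454,0.071,93.37,96.16,95.87,25.34
PspectrumV,vertical,16,1,83.03,0.952127,0.033,96.8054,98.86,98.67,51.28
PowerV,vertical,17,1,81.72,1.1841,0,45.87,98.57,98.39,45.87
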