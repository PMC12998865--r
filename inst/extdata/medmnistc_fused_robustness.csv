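dataset,clean_error,be,rbe
BloodMNIST,0.012,2.103,2.654
BreastMNIST,0.204,1.591,3.243
DermaMNIST,0.376,1.296,3.020
OCTMNIST,0.202,1.256,1.715
OrganAMNIST,0.092,2.225,2.992
OrganCMNIST,0.141,3.352,6.289
PathMNIST,0.035,0.517,0.663
PneumoniaMNIST,0.093,2.085,-6.210
RetinaMNIST,0.505,1.067,2.426
TissueMNIST,0.421,1.481,3.082
OrganSMNIST,0.272,1.256,2.065
ChestMNIST,0.461,1.424,2.930
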