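dataset,model,transform,segment_s,patient,accuracy,sensitivity,specificity
chbmit,vgg16,cwt,1,chb01,99.88,99.9,99.85
chbmit,vgg16,cwt,1,chb02,92.71,95.56,90.2
chbmit,vgg16,cwt,1,chb03,99.77,99.72,99.83
chbmit,vgg16,cwt,1,chb04,59.6,93.52,55.39
chbmit,vgg16,cwt,1,chb05,98.61,99.58,97.68
chbmit,vgg16,cwt,1,chb06,80.5,82.43,78.78
chbmit,vgg16,cwt,1,chb07,96.32,97.57,95.13
chbmit,vgg16,cwt,1,chb08,100,100,100
chbmit,vgg16,cwt,1,chb09,98.93,99.73,98.15
chbmit,vgg16,cwt,1,chb10,77.16,74.38,80.66
chbmit,vgg16,cwt,1,chb11,100,100,100
chbmit,vgg16,cwt,1,chb12,97.2,97.84,96.48
chbmit,vgg16,cwt,1,chb13,88.68,98.69,82.08
chbmit,vgg16,cwt,1,chb14,93.13,91.32,95.11
chbmit,vgg16,cwt,1,chb15,89.86,94.06,86.39
chbmit,vgg16,cwt,1,chb16,78.21,70.8,93.81
chbmit,vgg16,cwt,1,chb17,99.74,100,99.48
chbmit,vgg16,cwt,1,chb18,97.55,98.46,96.67
chbmit,vgg16,cwt,1,chb19,99.69,99.38,100
chbmit,vgg16,cwt,1,chb20,100,100,100
chbmit,vgg16,cwt,1,chb21,83.39,79.87,87.85
chbmit,vgg16,cwt,1,chb22,97.11,98.12,96.13
chbmit,vgg16,cwt,1,chb23,96.79,95.8,97.81
chbmit,vgg16,swt,1,chb01,99.9,99.95,99.85
chbmit,vgg16,swt,1,chb02,93.97,93.11,94.8
chbmit,vgg16,swt,1,chb03,99.86,99.71,100
chbmit,vgg16,swt,1,chb04,98.2,98.84,97.52
chbmit,vgg16,swt,1,chb05,88.47,92.1,85.42
chbmit,vgg16,swt,1,chb06,82.41,84.39,80.65
chbmit,vgg16,swt,1,chb07,86.45,85.7,87.23
chbmit,vgg16,swt,1,chb08,100,100,100
chbmit,vgg16,swt,1,chb09,97.5,96.9,98.14
chbmit,vgg16,swt,1,chb10,68.2,72.24,65.41
chbmit,vgg16,swt,1,chb11,99.27,98.56,100
chbmit,vgg16,swt,1,chb12,99.5,99.81,99.17
chbmit,vgg16,swt,1,chb13,94.31,94.43,94.2
chbmit,vgg16,swt,1,chb14,94.1,93.41,94.83
chbmit,vgg16,swt,1,chb15,84.42,88.64,81.03
chbmit,vgg16,swt,1,chb16,77.47,70,93.83
chbmit,vgg16,swt,1,chb17,93.82,89.55,99.12
chbmit,vgg16,swt,1,chb18,94.8,93.3,96.41
chbmit,vgg16,swt,1,chb19,99.38,98.77,100
chbmit,vgg16,swt,1,chb20,99.89,99.83,99.94
chbmit,vgg16,swt,1,chb21,83.04,82.34,83.76
chbmit,vgg16,swt,1,chb22,89.08,89.71,88.47
chbmit,vgg16,swt,1,chb23,93.25,90.9,95.9
chbmit,vgg16,cwt,3,chb01,100,100,100
chbmit,vgg16,cwt,3,chb02,82,99.03,63.92
chbmit,vgg16,cwt,3,chb03,97.6,96.09,99.54
chbmit,vgg16,cwt,3,chb04,70.56,50,90.22
chbmit,vgg16,cwt,3,chb05,95.68,96.12,95.3
chbmit,vgg16,cwt,3,chb06,88.6,84.88,92.57
chbmit,vgg16,cwt,3,chb07,95.83,98.33,93.33
chbmit,vgg16,cwt,3,chb08,99.17,98.3,100
chbmit,vgg16,cwt,3,chb09,99.72,99.43,100
chbmit,vgg16,cwt,3,chb10,93.13,95.2,91.26
chbmit,vgg16,cwt,3,chb11,100,100,100
chbmit,vgg16,cwt,3,chb12,99.17,98.77,99.54
chbmit,vgg16,cwt,3,chb13,95.83,92.09,99.45
chbmit,vgg16,cwt,3,chb14,83.45,74.5,92.91
chbmit,vgg16,cwt,3,chb15,96.38,93.75,99
chbmit,vgg16,cwt,3,chb16,90.21,94.62,85
chbmit,vgg16,cwt,3,chb17,93,90.48,97.3
chbmit,vgg16,cwt,3,chb18,98.75,99.23,98.18
chbmit,vgg16,cwt,3,chb19,100,100,100
chbmit,vgg16,cwt,3,chb20,100,100,100
chbmit,vgg16,cwt,3,chb21,85.56,95.45,76.09
chbmit,vgg16,cwt,3,chb22,96.25,97.5,95
chbmit,vgg16,cwt,3,chb23,97.27,96.12,98.29
chbmit,vgg16,swt,3,chb01,100,100,100
chbmit,vgg16,swt,3,chb02,90.5,90.29,90.72
chbmit,vgg16,swt,3,chb03,91.8,86.48,98.63
chbmit,vgg16,swt,3,chb04,100,100,100
chbmit,vgg16,swt,3,chb05,96.59,96.12,97.01
chbmit,vgg16,swt,3,chb06,90.7,85.55,96.16
chbmit,vgg16,swt,3,chb07,99.17,99.17,99.17
chbmit,vgg16,swt,3,chb08,99.72,99.43,100
chbmit,vgg16,swt,3,chb09,98.89,98.86,98.91
chbmit,vgg16,swt,3,chb10,93.75,96.05,91.53
chbmit,vgg16,swt,3,chb11,99.17,98.36,100
chbmit,vgg16,swt,3,chb12,98.33,97.79,98.85
chbmit,vgg16,swt,3,chb13,94.09,88.7,99.18
chbmit,vgg16,swt,3,chb14,87.41,84.23,90.78
chbmit,vgg16,swt,3,chb15,96.88,97.75,96
chbmit,vgg16,swt,3,chb16,79.38,96.15,59.55
chbmit,vgg16,swt,3,chb17,95,100,86.49
chbmit,vgg16,swt,3,chb18,99.17,98.85,99.55
chbmit,vgg16,swt,3,chb19,100,100,100
chbmit,vgg16,swt,3,chb20,99.8,100,99.54
chbmit,vgg16,swt,3,chb21,81.67,69.89,92.93
chbmit,vgg16,swt,3,chb22,93.75,90.83,96.67
chbmit,vgg16,swt,3,chb23,99.09,99.03,99.15
chbmit,mlf_cnn,swt,1,chb01,99.9,99.9,99.9
chbmit,mlf_cnn,swt,1,chb02,94.58,98.05,91.58
chbmit,mlf_cnn,swt,1,chb03,99.94,100,99.89
chbmit,mlf_cnn,swt,1,chb04,98.44,97.46,99.45
chbmit,mlf_cnn,swt,1,chb05,84.58,86.19,83.11
chbmit,mlf_cnn,swt,1,chb06,80.74,78.75,83.04
chbmit,mlf_cnn,swt,1,chb07,90.13,94.59,86.48
chbmit,mlf_cnn,swt,1,chb08,99.29,100,98.59
chbmit,mlf_cnn,swt,1,chb09,96.88,98.79,95.1
chbmit,mlf_cnn,swt,1,chb10,79.1,86.56,74.17
chbmit,mlf_cnn,swt,1,chb11,100,100,100
chbmit,mlf_cnn,swt,1,chb12,98.5,99.12,97.9
chbmit,mlf_cnn,swt,1,chb13,93.75,92.43,95.15
chbmit,mlf_cnn,swt,1,chb14,83.54,87.86,80.1
chbmit,mlf_cnn,swt,1,chb15,88.02,92.69,84.27
chbmit,mlf_cnn,swt,1,chb16,83.68,82.14,85.38
chbmit,mlf_cnn,swt,1,chb17,99.47,99.21,99.74
chbmit,mlf_cnn,swt,1,chb18,90.19,95.72,85.86
chbmit,mlf_cnn,swt,1,chb19,100,100,100
chbmit,mlf_cnn,swt,1,chb20,99.71,99.88,99.54
chbmit,mlf_cnn,swt,1,chb21,81.83,80.97,82.74
chbmit,mlf_cnn,swt,1,chb22,95.72,97.02,94.49
chbmit,mlf_cnn,swt,1,chb23,94.93,94.48,95.38
chbmit,mlf_cnn,swt,3,chb01,100,100,100
chbmit,mlf_cnn,swt,3,chb02,97,97.09,96.91
chbmit,mlf_cnn,swt,3,chb03,99.6,99.29,100
chbmit,mlf_cnn,swt,3,chb04,100,100,100
chbmit,mlf_cnn,swt,3,chb05,95.68,93.69,97.44
chbmit,mlf_cnn,swt,3,chb06,93.37,90.07,96.88
chbmit,mlf_cnn,swt,3,chb07,98.75,99.17,98.33
chbmit,mlf_cnn,swt,3,chb08,100,100,100
chbmit,mlf_cnn,swt,3,chb09,98.89,98.86,98.91
chbmit,mlf_cnn,swt,3,chb10,93.75,94.35,93.17
chbmit,mlf_cnn,swt,3,chb11,100,100,100
chbmit,mlf_cnn,swt,3,chb12,99.17,100,98.38
chbmit,mlf_cnn,swt,3,chb13,98.06,98.02,98.09
chbmit,mlf_cnn,swt,3,chb14,84.83,82.89,86.88
chbmit,mlf_cnn,swt,3,chb15,95.34,93.42,97.46
chbmit,mlf_cnn,swt,3,chb16,92.71,95.38,89.55
chbmit,mlf_cnn,swt,3,chb17,99,100,97.3
chbmit,mlf_cnn,swt,3,chb18,98.75,98.46,99.09
chbmit,mlf_cnn,swt,3,chb19,100,100,100
chbmit,mlf_cnn,swt,3,chb20,100,100,100
chbmit,mlf_cnn,swt,3,chb21,93.89,89.2,98.37
chbmit,mlf_cnn,swt,3,chb22,95,92.5,97.5
chbmit,mlf_cnn,swt,3,chb23,97.05,96.6,97.44
zju4h,mlf_cnn,swt,1,pa01,92.31,90.54,96.27
zju4h,mlf_cnn,swt,1,pa02,84.73,97.26,82.73
zju4h,mlf_cnn,swt,1,pa03,99.72,99.43,100
zju4h,mlf_cnn,swt,1,pa04,91.56,94.44,88.68
zju4h,mlf_cnn,swt,1,pa05,99.44,100,98.91
zju4h,mlf_cnn,swt,1,pa06,99.33,99.33,99.33
zju4h,mlf_cnn,swt,1,pa07,86.94,97.73,86.63
zju4h,mlf_cnn,swt,1,pa08,100,100,100
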