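item,parameter,estimate,rse
IPSS1,a,1.19,7.3
IPSS1,b1,-4.56,6
IPSS1,b2,2.02,7.3
IPSS1,b3,1.86,6.8
IPSS1,b4,1.57,7
IPSS1,b5,1.40,8.1
IPSS2,a,1.04,6.8
IPSS2,b1,-5.55,6
IPSS2,b2,2.65,7.3
IPSS2,b3,2.06,6.7
IPSS2,b4,1.49,7
IPSS2,b5,1.53,7.5
IPSS3,a,1.04,7.5
IPSS3,b1,-4.31,6
IPSS3,b2,2.09,7.4
IPSS3,b3,1.85,7.1
IPSS3,b4,1.23,7.5
IPSS3,b5,1.53,8.2
IPSS4,a,0.929,6.9
IPSS4,b1,-4.09,5.8
IPSS4,b2,2.14,7
IPSS4,b3,1.74,6.8
IPSS4,b4,1.26,7.4
IPSS4,b5,1.45,7.9
IPSS5,a,0.972,7
IPSS5,b1,-5.68,6.2
IPSS5,b2,2.56,7.7
IPSS5,b3,1.87,7
IPSS5,b4,1.45,7.1
IPSS5,b5,1.23,7.7
IPSS6,a,0.774,8.1
IPSS6,b1,-3.55,6.3
IPSS6,b2,2.01,8
IPSS6,b3,1.96,7.9
IPSS6,b4,1.96,8.6
IPSS6,b5,1.96,10.3
IPSS7,a,0.549,7.6
IPSS7,b1,-7.52,6.8
IPSS7,b2,4.79,7.9
IPSS7,b3,3.28,7.4
IPSS7,b4,2.26,8.1
IPSS7,b5,1.91,9.9
QoL,a,1.22,6.4
QoL,b1,-7.26,6.3
QoL,b2,2.88,9.4
QoL,b3,1.97,6.8
QoL,b4,1.82,6.4
QoL,b5,1.38,6.7
QoL,b6,1.61,7.5
BII,a,0.975,7.9
BII,b1,-5.18,6.6
BII,b2,0.974,13.8
BII,b3,0.943,11.8
BII,b4,0.828,11.1
BII,b5,0.775,10.4
BII,b6,0.549,11.4
BII,b7,0.552,11.1
BII,b8,0.789,10
BII,b9,1.28,9.7
BII,b10,0.685,14.5
BII,b11,0.91,15.5
BII,b12,1.03,20.1
BII,b13,2.48,28.8
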