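subject,first_acuity,last_acuity
1,1.22,1.0399999999999998
2,1.24,1.0699999999999998
3,1.26,1.0999999999999999
4,1.27,1.1199999999999999
5,1.29,1.14
6,1.3,1.16
7,1.32,1.19
8,1.34,1.22
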