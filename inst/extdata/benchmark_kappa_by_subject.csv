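subject,CSP,ICA+Wavelet-CSP,ORICA+CSP
A01,0.69,0.75,0.79
A02,0.34,0.61,0.76
A03,0.71,0.80,0.86
A04,0.44,0.63,0.71
A05,0.16,0.57,0.69
A06,0.21,0.52,0.61
A07,0.66,0.77,0.82
A08,0.73,0.74,0.81
A09,0.69,0.72,0.76
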