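subject,LDA,SVM,A-LDA,A-SVM
A01,246.39,365.33,313.33,366.60
A02,251.08,350.44,356.57,382.16
A03,266.46,336.11,329.13,340.83
A04,272.39,331.44,277.41,375.60
A05,218.62,351.66,304.58,394.29
A06,253.91,338.46,315.55,316.66
A07,264.50,355.34,314.44,355.34
A08,253.91,323.42,327.98,351.66
A09,239.02,371.71,281.47,360.30
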