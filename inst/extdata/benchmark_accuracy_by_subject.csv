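subject,LDA,SVM,A-LDA,A-SVM
A01,79,90,85.6,90.1
A02,79.5,88.8,89.3,91.3
A03,81.1,87.6,87,88
A04,81.7,87.2,82.2,90.8
A05,75.9,88.9,84.8,92.2
A06,79.8,87.8,85.8,85.9
A07,80.9,89.2,85.7,89.2
A08,79.8,86.5,86.9,88.9
A09,78.2,90.5,82.6,89.6
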