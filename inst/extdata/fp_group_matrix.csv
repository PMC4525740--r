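criterion,Individual Characteristics,Patient-Doctor relationship,Professional Characteristics,The Setting,Ethical Characteristics
Individual Characteristics,1,1/3,1/5,3,2
Patient-Doctor relationship,3,1,1/3,4,2
Professional Characteristics,5,3,1,5,3
The Setting,1/3,1/4,1/5,1,1
Ethical Characteristics,1/2,1/2,1/3,1,1
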