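example_imi 12 1000 4000
example_imi.dat 16 2000/mV 16 0 0 0 0 i
example_imi.dat 16 2000/mV 16 0 0 0 0 ii
example_imi.dat 16 2000/mV 16 0 0 0 0 iii
example_imi.dat 16 2000/mV 16 0 0 0 0 avr
example_imi.dat 16 2000/mV 16 0 0 0 0 avl
example_imi.dat 16 2000/mV 16 0 0 0 0 avf
example_imi.dat 16 2000/mV 16 0 0 0 0 v1
example_imi.dat 16 2000/mV 16 0 0 0 0 v2
example_imi.dat 16 2000/mV 16 0 0 0 0 v3
example_imi.dat 16 2000/mV 16 0 0 0 0 v4
example_imi.dat 16 2000/mV 16 0 0 0 0 v5
example_imi.dat 16 2000/mV 16 0 0 0 0 v6
# age: 63
# sex: male
# Reason for admission: Myocardial infarction
# Acute infarction (localization): inferior
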