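example_excluded 12 1000 4000
example_excluded.dat 16 2000/mV 16 0 0 0 0 i
example_excluded.dat 16 2000/mV 16 0 0 0 0 ii
example_excluded.dat 16 2000/mV 16 0 0 0 0 iii
example_excluded.dat 16 2000/mV 16 0 0 0 0 avr
example_excluded.dat 16 2000/mV 16 0 0 0 0 avl
example_excluded.dat 16 2000/mV 16 0 0 0 0 avf
example_excluded.dat 16 2000/mV 16 0 0 0 0 v1
example_excluded.dat 16 2000/mV 16 0 0 0 0 v2
example_excluded.dat 16 2000/mV 16 0 0 0 0 v3
example_excluded.dat 16 2000/mV 16 0 0 0 0 v4
example_excluded.dat 16 2000/mV 16 0 0 0 0 v5
example_excluded.dat 16 2000/mV 16 0 0 0 0 v6
# age: 71
# sex: female
# Reason for admission: Myocardial infarction
# Acute infarction (localization): infero-postero-lateral
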