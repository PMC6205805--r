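# Synthetic presampling MTF curve (NOT a measurement): frequency [cycles/mm], value
0.0 1.00
1.0 0.92
2.0 0.78
3.0 0.62
4.0 0.47
5.0 0.34
6.0 0.24
7.0 0.16
8.0 0.11
9.0 0.07
10.0 0.05
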