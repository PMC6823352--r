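14087311	315295	8187
233156	12800870	116645
39181	243181	1136074
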