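wavenumber,assignment
857.9,synthetic standard line 1
968.7,synthetic standard line 2
1168.5,synthetic standard line 3
1236.8,synthetic standard line 4
1323.9,synthetic standard line 5
1561.5,synthetic standard line 6
1648.4,synthetic standard line 7
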