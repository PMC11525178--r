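"time_min","width_um"
0,180
30,173
60,169.4
90,167.5
120,166.6
150,166.1
180,165.9
210,165.7
240,165.7
270,165.6
300,165.6
330,165.6
360,165.6
390,165.6
420,165.6
450,165.6
480,165.6
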