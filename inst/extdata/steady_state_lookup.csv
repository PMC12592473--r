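"n_beads","length","width","tau"
40,13.5317434255294,6.40221315666927,NA
70,15.9882142941137,9.1274680133255,NA
100,25.9419712179209,10.3639876732896,NA
120,25.6236863994643,10.673156087777,NA
250,32.4956291659808,17.3296793557287,97.2798743969722
500,51.5865391391746,30.7568034405438,NA
1000,107.423255344397,41.0524192565692,NA
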