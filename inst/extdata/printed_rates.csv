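reactor,lin_rate,lin_sd,lin_adj_r2,mb_rate
1,1.548,0.090,0.958,0.35
2,1.920,0.124,0.952,0.27
3,1.630,0.277,0.794,0.62
4,1.911,0.114,0.969,0.52
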