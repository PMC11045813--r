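video,duration_s,gt_count,rate_per_s,fps
Video-1,55,4,0.0727,60
Video-2,91,6,0.0659,60
Video-3,450,36,0.0800,60
Video-4,490,40,0.0816,60
Video-5,389,23,0.0591,60
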