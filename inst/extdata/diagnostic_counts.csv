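method,comparison,parameter,n_tp,n_fn,h_tn,h_fp,se_printed,sp_printed,ac_printed
JT,stage1,LB,23,3,23,3,88.5,88.5,88.5
JT,stage2,LB,25,1,24,2,96.2,88.5,94.2
JT,stage_diff,LB,24,2,24,2,92.3,92.3,92.3
MMT,stage1,LB,20,6,20,6,76.9,76.9,76.9
MMT,stage2,LB,23,3,22,4,88.5,84.6,86.5
MMT,stage_diff,LB,21,5,22,4,80.8,84.6,82.7
JT,stage1,CB,24,2,23,3,92.3,88.5,90.4
JT,stage2,CB,25,1,25,1,96.2,96.2,96.2
JT,stage_diff,CB,25,1,24,2,96.2,92.3,94.2
MMT,stage1,CB,21,5,20,6,80.8,76.9,78.8
MMT,stage2,CB,24,2,22,4,92.3,84.6,88.5
MMT,stage_diff,CB,23,3,21,5,88.5,80.8,84.6
JT,stage1,LD,22,4,21,5,84.6,80.8,82.7
JT,stage2,LD,25,1,23,3,96.2,88.5,92.3
JT,stage_diff,LD,23,3,24,2,88.5,92.3,90.4
MMT,stage1,LD,18,8,19,7,69.2,73.1,71.2
MMT,stage2,LD,20,6,20,6,76.9,76.9,76.9
MMT,stage_diff,LD,17,9,16,10,65.4,61.5,63.5
JT,stage1,CD,23,3,23,3,88.5,88.5,88.5
JT,stage2,CD,24,2,25,1,92.3,96.2,94.2
JT,stage_diff,CD,24,2,24,2,92.3,92.3,92.3
MMT,stage1,CD,19,7,18,8,73.1,69.2,71.2
MMT,stage2,CD,20,6,19,7,76.9,73.1,75.0
MMT,stage_diff,CD,19,7,18,8,73.1,69.2,71.2
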