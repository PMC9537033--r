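id,ct_scan,precision,recall,f_measure
1,LIDC-IDRI-0260,0.9805,0.8653,0.9513
2,LIDC-IDRI-0195,0.9509,0.8369,0.9219
3,LIDC-IDRI-0060,0.9847,0.6898,0.8963
4,LIDC-IDRI-0045,0.9624,0.8209,0.9256
5,LIDC-IDRI-0044,0.9850,0.8845,0.9599
6,LIDC-IDRI-0003,0.9521,0.8407,0.9238
7,LIDC-IDRI-0186,0.9899,0.4624,0.7837
8,LIDC-IDRI-0087,0.8487,0.8197,0.8418
9,LIDC-IDRI-0884,0.9403,0.9214,0.9359
10,LIDC-IDRI-0052,0.8395,0.7260,0.8103
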