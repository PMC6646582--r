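subject_id,condition,variable,A_pct,tau_s,r_squared
S01,HF,IMVC,64,34,0.81
S01,HF,QTW,71,31,0.94
S01,HF,VA,69,95,0.81
S01,LF,IMVC,47,42,0.98
S01,LF,QTW,67,79,0.95
S01,LF,VA,68,107,0.94
S02,HF,IMVC,65,52,0.96
S02,HF,QTW,76,76,0.92
S02,HF,VA,83,18,0.96
S02,LF,IMVC,53,75,0.96
S02,LF,QTW,59,49,0.98
S02,LF,VA,88,161,0.96
S03,HF,IMVC,66,32,0.92
S03,HF,QTW,77,56,0.9
S03,HF,VA,85,8,0.83
S03,LF,IMVC,45,65,0.98
S03,LF,QTW,56,25,0.98
S03,LF,VA,79,106,0.76
S04,HF,IMVC,73,19,0.72
S04,HF,QTW,63,75,0.89
S04,HF,VA,83,14,0.76
S04,LF,IMVC,56,19,0.98
S04,LF,QTW,58,91,0.98
S04,LF,VA,81,131,0.61
S05,HF,IMVC,70,17,0.69
S05,HF,QTW,84,75,0.96
S05,HF,VA,56,11,0.98
S05,LF,IMVC,32,117,0.88
S05,LF,QTW,71,68,0.91
S05,LF,VA,67,110,0.99
S06,HF,IMVC,63,25,0.94
S06,HF,QTW,74,48,0.96
S06,HF,VA,90,71,0.92
S06,LF,IMVC,63,23,0.98
S06,LF,QTW,70,23,0.98
S06,LF,VA,80,42,0.92
S07,HF,IMVC,74,12,0.9
S07,HF,QTW,75,66,0.97
S07,HF,VA,83,10,0.81
S07,LF,IMVC,55,37,0.88
S07,LF,QTW,73,28,0.96
S07,LF,VA,57,133,0.9
S08,HF,IMVC,59,33,0.98
S08,HF,QTW,77,59,0.94
S08,HF,VA,74,51,0.92
S08,LF,IMVC,51,24,0.94
S08,LF,QTW,70,8,0.88
S08,LF,VA,60,41,0.79
S09,HF,IMVC,73,61,0.9
S09,HF,QTW,73,51,0.9
S09,HF,VA,91,32,0.94
S09,LF,IMVC,76,45,0.92
S09,LF,QTW,70,51,0.86
S09,LF,VA,82,33,0.83
S10,HF,IMVC,51,33,0.94
S10,HF,QTW,55,16,0.9
S10,HF,VA,97,80,0.98
S10,LF,IMVC,41,90,0.96
S10,LF,QTW,58,75,0.98
S10,LF,VA,59,136,0.63
S11,HF,IMVC,70,17,0.81
S11,HF,QTW,77,30,0.99
S11,HF,VA,78,60,0.89
S11,LF,IMVC,65,62,0.9
S11,LF,QTW,61,29,0.98
S11,LF,VA,81,62,0.96
S12,HF,IMVC,55,24,0.85
S12,HF,QTW,73,17,0.96
S12,HF,VA,84,70,0.81
S12,LF,IMVC,46,29,0.98
S12,LF,QTW,79,14,0.88
S12,LF,VA,61,27,0.83
S13,HF,IMVC,48,42,0.96
S13,HF,QTW,50,42,0.98
S13,HF,VA,97,35,0.99
S13,LF,IMVC,56,27,0.96
S13,LF,QTW,41,28,0.94
S13,LF,VA,97,86,0.88
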