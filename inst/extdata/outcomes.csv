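material_id,outcome,timepoint_day,value,unit,control_mean,control_se,n,provenance
asbestos,PMN,1,1,fold vs asbestos,,,6,printed
CNF,PMN,1,2.8,fold vs asbestos,,,6,printed
SWCNT,PMN,1,5.7,fold vs asbestos,,,6,printed
SWCNT,PMN_fold_control,1,700,fold of control,1.58,0.69,6,printed
CNF,PMN_fold_control,1,150,fold of control,1.58,0.69,6,printed
asbestos,PMN_fold_control,7,675,fold of control,1.39,0.45,6,printed
CNF,PMN_fold_control,28,25,fold of control,0.71,0.24,6,printed
SWCNT,AM,7,1.6,fold of control,345.01,30.01,6,printed
CNF,AM,7,2.0,fold of control,345.01,30.01,6,printed
CNF,AM,28,1.6,fold of control,229.79,27.81,6,printed
SWCNT,protein,1,3.75,fold of control,0.31,0.05,6,printed
CNF,protein,1,1.86,fold of control,0.31,0.05,6,printed
asbestos,protein,1,1.0,fold of control,0.31,0.05,6,reconstructed
SWCNT,protein,7,2.5,fold of control,0.33,0.05,6,printed
CNF,protein,7,1.75,fold of control,0.33,0.05,6,printed
asbestos,protein,7,2.05,fold of control,0.33,0.05,6,printed
SWCNT,protein,28,2.6,fold of control,0.38,0.05,6,printed
CNF,protein,28,1.14,fold of control,0.38,0.05,6,printed
CNF,LDH,1,1.8,fold of control,25.12,0.70,6,printed
CNF,LDH,7,1.8,fold of control,26.81,1.03,6,printed
CNF,LDH,28,1.5,fold of control,25.47,1.06,6,printed
SWCNT,4HNE,1,9.5,fold of control,,,6,printed
CNF,4HNE,1,6,fold of control,,,6,printed
asbestos,4HNE,1,1.0,fold of control,,,6,reconstructed
SWCNT,4HNE,7,10.0,fold of control,,,6,printed
CNF,4HNE,7,4,fold of control,,,6,printed
asbestos,4HNE,7,1.0,fold of control,,,6,reconstructed
SWCNT,4HNE,28,6.0,fold of control,,,6,printed
CNF,4HNE,28,1.0,fold of control,,,6,printed
asbestos,4HNE,28,11,fold of control,,,6,printed
SWCNT,carbonyl,1,4.8,fold of control,,,6,printed
CNF,carbonyl,1,1.8,fold of control,,,6,printed
asbestos,carbonyl,1,1.8,fold of control,,,6,printed
SWCNT,carbonyl,7,3.5,fold of control,,,6,printed
CNF,carbonyl,7,1.8,fold of control,,,6,printed
asbestos,carbonyl,7,1.8,fold of control,,,6,printed
SWCNT,carbonyl,28,3.5,fold of control,,,6,printed
CNF,carbonyl,28,1.8,fold of control,,,6,printed
asbestos,carbonyl,28,1.8,fold of control,,,6,printed
SWCNT,TGFb1,1,2.5,fold of control,,,6,printed
SWCNT,TGFb1,7,4.5,fold of control,,,6,printed
CNF,TGFb1,7,2.0,fold of control,,,6,printed
asbestos,TGFb1,7,2.0,fold of control,,,6,printed
SWCNT,TGFb1,28,1.25,fold of control,,,6,printed
SWCNT,collagen,28,5.8,fold of control,,,6,printed
CNF,collagen,28,3,fold of control,,,6,printed
asbestos,collagen,28,2.8,fold of control,,,6,printed
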