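name,cas,formula,formula_printed,class,chain_n,ether_r,rt_min,precursor_mz,product_mz,ce_ev,internal_standard,mz_flag,slope,intercept,linear_min_ugl,linear_max_ugl,lod_ngl,loq_ngl
PFBA,375-22-4,C4HF7O2,C4HF7O2,PFCA,3,,3.83,212.9792,168.9883,10,13C4-PFBA,TRUE,0.08637,-0.03600,1.0,20,0.2,0.6
PFPeA,2706-90-3,C5HF9O2,C5HF9O2,PFCA,4,,6.11,262.9760,218.9857,10,13C5-PFPeA,FALSE,0.01029,-0.009238,0.2,20,0.2,0.6
PFBS,375-73-5,C4HF9O3S,C4HF9O3S,PFSA,4,,6.42,298.9430,79.9558,50,13C3-PFBS,TRUE,0.1116,0.01691,0.2,20,0.02,0.06
PFHxA,307-24-4,C6HF11O2,C6HF11O2,PFCA,5,,7.18,312.9728,268.983,10,13C5-PFHxA,FALSE,0.1024,-0.009931,0.2,20,0.02,0.06
PFPeS,2706-91-4,C5HF11O3S,C5HF11O3S,PFSA,5,,7.31,348.9398,79.9559,45,13C5-PFHxA,TRUE,8.1727,0.3959,0.2,10,0.02,0.06
HFPO-DA,13252-13-6,C6HF11O3,C6HF11O3,EtherPFCA,3,C3F7,7.39,328.9677,168.9883,10,13C5-PFHxA,TRUE,0.01346,-0.004076,0.2,20,0.02,0.06
FBSA,30334-69-1,C4H2F9NO2S,4H2F9NO2S,PFSAmide,4,,7.41,297.9590,77.9640,33,13C4-PFHpA,TRUE,3.5356,-0.01291,0.2,20,0.02,0.06
PFHpA,375-85-9,C7HF13O2,C7HF13O2,PFCA,6,,7.86,362.9706,318.9798,10,13C4-PFHpA,FALSE,0.09724,-0.002587,0.2,20,0.02,0.06
DONA,919005-14-4,C7H2F12O4,C7H2F12O4,EtherPFCA,1,CF3;C4F9O,7.86,376.9689,250.9757,10,13C3-PFHxS,FALSE,0.6623,-0.01714,0.2,20,0.02,0.06
PFHxS,355-46-4,C6HF13O3S,C6HF13O3S,PFSA,6,,7.89,398.9365,79.9558,45,13C3-PFHxS,TRUE,0.1117,0.02483,0.2,20,0.02,0.06
PFOA,335-67-1,C8HF15O2,C8HF15O2,PFCA,7,,8.32,412.9664,368.9765,10,13C8-PFOA,FALSE,0.08905,0.001332,0.2,20,0.02,0.06
PFHpS,375-92-8,C7HF15O3S,C7HF15O3S,PFSA,7,,8.34,448.9333,79.9559,40,13C8-PFOA,TRUE,2.4879,-0.001287,0.2,20,0.02,0.06
6:2FTSA,27619-94-9,C8H5F13O3S,C8H4F13NaO3S,FTSA,6,,8.32,426.9674,406.9615,20,13C8-PFOA,FALSE,0.1984,-0.01572,0.2,10,0.02,0.06
PFNA,375-95-1,C9HF17O2,C9HF17O2,PFCA,8,,8.72,462.9632,418.9743,10,13C9-PFNA,TRUE,0.09053,0.001235,0.2,20,0.02,0.06
PFOS,1763-23-1,C8HF17O3S,C8HF17O3S,PFSA,8,,8.72,498.9308,79.9558,38,13C8-PFOS,TRUE,0.1155,0.003238,0.2,20,0.02,0.06
6:2Cl-PFESA,73606-19-6,C8HClF16O4S,C8ClF16KO4S,ClPFESA,0,C6ClF12,8.88,530.8956,350.9452,20,13C8-PFOS,FALSE,0.2260,0.005032,0.2,20,0.02,0.06
PFNS,68259-12-1,C9HF19O3S,C9HF19O3S,PFSA,9,,9.06,548.9270,79.9558,35,13C6-PFDA,TRUE,0.5627,-0.007492,0.2,10,0.02,0.06
PFDA,335-76-2,C10HF19O2,C10HF19O2,PFCA,9,,9.05,512.9600,468.9701,10,13C6-PFDA,FALSE,0.9151,-0.0005316,0.2,20,0.02,0.06
PFUdA,2058-94-8,C11HF21O2,C11HF21O2,PFCA,10,,9.34,562.9568,518.9674,10,13C7-PFUdA,FALSE,0.9988,-0.009644,0.2,20,0.02,0.06
PFDS,335-77-3,C10HF21O3S,C10HF21O3S,PFSA,10,,9.32,598.9238,79.9558,35,13C7-PFUdA,TRUE,0.4706,0.02052,0.2,20,0.02,0.06
8:2Cl-PFESA,83329-89-9,C10HClF20O4S,C10ClF20KO4S,ClPFESA,0,C8ClF16,9.41,630.8895,450.9390,15,13C7-PFUdA,FALSE,0.03039,0.00007281,0.2,20,0.02,0.06
PFDoA,307-55-1,C12HF23O2,C12HF23O2,PFCA,11,,9.56,612.9537,568.9641,10,13C2-PFDoA,FALSE,0.08742,0.002574,0.2,20,0.02,0.06
PFTrDA,72629-94-8,C13HF25O2,C13HF25O2,PFCA,12,,9.77,662.9504,618.9609,15,13C2-PFTrDA,FALSE,0.03162,0.00009824,0.2,10,0.02,0.06
PFTeDA,376-06-7,C14HF27O2,C14HF27O2,PFCA,13,,9.96,712.9473,668.9577,10,13C2-PFTeDA,FALSE,0.08930,0.0003450,0.2,10,0.02,0.06
PFHxDA,67905-19-5,C16HF31O2,C16HF31O2,PFCA,15,,10.37,812.9409,768.9514,10,13C2-PFTeDA,FALSE,0.06434,-0.001564,0.2,20,0.02,0.06
PFOdA,16517-11-6,C18HF35O2,C18HF35O2,PFCA,17,,10.92,912.9345,868.9446,10,13C2-PFTeDA,FALSE,0.03345,0.04086,0.2,20,0.2,0.6
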