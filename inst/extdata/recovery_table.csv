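name,background_ngl,mean_1,recovery_1,rsd_1,mean_5,recovery_5,rsd_5,mean_10,recovery_10,rsd_10
PFBA,n.d.,1.04,104.9,5.2,5.00,99.9,3.9,9.40,94.0,3.8
PFPeA,n.d.,0.92,91.6,4.4,4.12,82.5,3.7,8.34,83.3,3.2
PFBS,n.d.,0.98,97.6,1.3,4.72,94.2,1.7,8.94,89.4,1.6
PFHxA,n.d.,1.00,99.1,2.9,4.68,93.4,2.4,8.92,89.1,1.4
PFPeS,n.d.,0.74,74.3,3.1,4.04,80.8,3.6,8.74,87.4,2.8
HFPO-DA,n.d.,1.04,103.8,2.3,4.38,87.6,1.8,8.98,89.7,1.9
FBSA,n.d.,0.68,68.4,5.2,3.62,72.5,4.8,7.46,74.6,4.3
PFHpA,n.d.,1.04,104.3,3.4,4.54,90.6,4.1,9.60,96.0,3.8
DONA,n.d.,0.98,97.2,1.8,4.56,91.2,1.9,9.38,93.8,1.4
PFHxS,n.d.,0.94,93.1,1.9,4.08,81.7,1.1,8.52,85.2,1.4
PFOA,n.d.,0.90,90.8,4.2,4.72,94.2,4.6,9.08,90.7,3.8
PFHpS,n.d.,0.68,67.3,3.7,4.32,86.3,3.7,7.28,72.7,2.4
6:2FTSA,n.d.,0.88,87.9,4.9,4.58,91.7,3.7,9.64,96.4,4.1
PFNA,n.d.,0.94,93.4,3.6,4.72,94.2,3.7,9.14,91.3,2.9
PFOS,n.d.,1.06,105.7,2.6,4.66,93.2,1.3,8.74,87.3,1.5
6:2Cl-PFESA,n.d.,0.74,74.0,3.5,3.96,79.1,2.8,6.28,62.8,2.1
PFNS,n.d.,0.76,76.8,5.7,4.48,89.7,5.4,8.46,84.6,4.6
PFDA,n.d.,0.90,90.4,4.6,4.76,95.3,4.3,9.50,95.0,4.3
PFUdA,n.d.,1.00,99.3,3.2,4.78,95.7,1.5,8.90,89.0,1.7
PFDS,n.d.,0.82,81.3,3.3,3.80,75.9,3.5,7.62,76.1,1.7
8:2Cl-PFESA,n.d.,0.88,87.3,2.4,4.14,82.9,3.2,7.72,77.2,5.3
PFDoA,n.d.,1.20,119.2,5.3,5.02,100.2,5.5,9.38,93.7,4.2
PFTrDA,n.d.,1.04,103.4,6.3,4.82,96.5,4.7,9.12,91.1,4.5
PFTeDA,n.d.,1.18,118.7,4.2,5.20,104.1,3.9,8.90,88.9,3.8
PFHxDA,n.d.,0.66,66.3,6.8,3.64,72.6,6.1,7.48,74.7,6.5
PFOdA,n.d.,0.74,73.5,7.3,4.08,81.6,5.2,8.42,84.1,5.7
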