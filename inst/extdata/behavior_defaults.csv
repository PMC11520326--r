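measure,assay,unit,mean_wt_baseline,se_wt_baseline,mean_ko_baseline,se_ko_baseline,mean_wt_final,se_wt_final,mean_ko_final,se_ko_final
Mean power simple,USV,dB/Hz,-88.2,1.3,-97.5,1.5,-93.6,1.3,-95.9,1.5
Mean power FM,USV,dB/Hz,-87.4,1.0,-96.9,1.1,-93.4,1.0,-95.1,1.1
Peak frequency simple,USV,kHz,55.8,1.5,55.2,1.7,56.0,1.5,57.4,1.7
Peak frequency FM,USV,kHz,65.0,1.5,61.5,1.6,66.0,1.5,62.3,1.6
Bandwidth simple,USV,kHz,12.44,0.89,11.3,1.0,11.46,0.89,11.7,1.0
Bandwidth FM,USV,kHz,24.4,1.1,15.4,1.2,21.4,1.1,17.5,1.2
Forelimb foot faults,beam,count,1.20,0.24,2.22,0.27,1.12,0.24,1.95,0.27
Hindlimb foot faults,beam,count,1.09,0.24,2.30,0.26,1.01,0.24,2.43,0.26
Time to traverse beam,beam,s,3.67,0.29,3.23,0.32,3.64,0.29,3.02,0.32
Time to traverse final third,beam,s,1.87,0.19,1.70,0.22,1.96,0.19,1.70,0.22
Forelimb up steps,cylinder,count,6.5,1.2,8.0,1.3,4.5,1.2,5.3,1.3
Forelimb down steps,cylinder,count,15.7,1.5,20.4,1.7,14.9,1.5,17.9,1.7
Hindlimb steps,cylinder,count,15.9,1.5,22.8,1.7,10.7,1.5,18.9,1.7
Rears,cylinder,count,10.6,0.9,15.2,1.0,8.87,0.90,13.2,1.0
Lands,cylinder,count,9.93,0.88,15.00,0.98,8.53,0.88,13.00,0.98
Long ITI dCorrect,5CSRTT,%,-11.8,6.7,1.7,4.7,-16.9,5.5,-4.7,4.7
Long ITI dIncorrect,5CSRTT,%,-0.3,3.1,-0.2,1.8,-2.4,2.2,3.5,1.8
Long ITI dPremature,5CSRTT,%,18,12,29.1,7.1,7.7,8.6,25.9,7.1
Long ITI dOmission,5CSRTT,%,11.7,5.7,-1.5,4.3,19.5,4.9,1.2,4.3
Short SD dCorrect,5CSRTT,%,-3.2,9.3,-1.7,5.5,-32.4,6.7,-29.1,5.5
Short SD dIncorrect,5CSRTT,%,-0.9,4.4,0.7,2.6,1.1,3.1,7.2,2.6
Short SD dPremature,5CSRTT,%,4.8,9.4,-3.6,5.6,-2.2,6.7,6.1,5.6
Short SD dOmission,5CSRTT,%,20.0,9.2,1.1,5.7,32.6,6.8,21.9,5.7
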