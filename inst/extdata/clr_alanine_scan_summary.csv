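ramp,ligand,mutant,n_cse,cse_pct,cse_sem,wt_pec50,wt_pec50_sem,mut_pec50,mut_pec50_sem,wt_emax_nM,wt_emax_sem,mut_emax_nM,mut_emax_sem,n_cre,printed_delta_log_ra,printed_delta_sem
RAMP1,CGRP,V190A,5,123.7,5.6,9.95,0.06,10.35,0.12,37.66,7.22,37.34,7.90,5,-0.49,0.15
RAMP1,CGRP,Y227A,5,99.2,7.53,10.10,0.11,9.23,0.15,36.34,8.51,32.99,9.43,5,0.91,0.26
RAMP1,CGRP,N305A,6,95.5,4.42,10.08,0.06,7.60,0.12,31.16,8.65,19.35,5.94,5,2.70,0.23
RAMP1,CGRP,L345A,6,96.1,6.69,10.18,0.15,8.29,0.08,27.99,8.60,19.96,7.11,5,2.05,0.28
RAMP1,CGRP,H374A,6,139.7,16.5,9.93,0.02,10.20,0.09,35.40,7.26,41.79,11.17,4,-0.49,0.20
RAMP1,AM,N305A,6,95.5,4.42,8.32,0.15,6.52,0.11,33.54,3.28,8.93,1.52,3,2.39,0.21
RAMP1,AM,H374A,6,139.7,16.5,8.43,0.14,10.44,0.20,26.98,9.13,37.28,12.87,5,-2.30,0.37
RAMP3,AM,Y227A,5,94.5,7.90,9.97,0.06,9.35,0.07,35.68,6.43,31.25,6.01,4,0.70,0.16
RAMP3,AM,N305A,5,103.1,20.7,9.86,0.09,8.34,0.07,36.04,7.60,11.06,2.56,4,2.02,0.21
RAMP3,AM,L345A,5,90.4,7.12,9.91,0.08,8.80,0.03,35.89,5.16,7.00,1.55,4,1.86,0.15
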