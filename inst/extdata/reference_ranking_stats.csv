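variable,label,n_unfavorable,n_total,chi_square,logrank_p,km_rank,is_months,is_rank,uni_p,uni_hr,uni_lo,uni_hi,uni_rank,multi_p,multi_hr,multi_lo,multi_hi,multi_rank,final_rank
nodes,Infiltrated lymph nodes of the primary tumor,233,371,21.6,0.0005,1,26.6,2,0.0005,1.65,1.3,2.0,2,0.0005,1.55,1.2,1.9,2,2
margin,Positive liver resection margin,44,371,20.0,0.0005,2,28.1,1,0.0005,2.04,1.5,2.8,1,0.0005,1.79,1.3,2.5,1,1
crp,C-reactive protein >= 6 mg/L,164,371,16.5,0.0005,3,20.6,3,0.0005,1.53,1.2,1.9,3,0.012,1.35,1.1,1.7,3,3
asa,ASA classification 2 or 3,213,371,8.4,0.004,4,16.6,4,0.004,1.35,1.1,1.7,4,0.009,1.33,1.1,1.6,4,4
albumin,Albumins <= 38 g/L,131,371,6.7,0.010,5,14.7,5,0.011,1.33,1.1,1.6,5,0.270,1.14,0.9,1.4,8,8
multiplicity,Multiple liver metastases,203,371,5.1,0.024,6,12.3,7,0.026,1.26,1.0,1.6,7,0.087,1.21,1.0,1.5,6,6
size,Largest liver metastasis >= 3.30 cm,187,371,4.8,0.028,7,11.1,8,0.030,1.25,1.0,1.5,8,0.217,1.14,0.9,1.4,7,7
right_side,Primary tumor on the right side,76,371,4.2,0.040,8,13.3,6,0.042,1.30,1.0,1.7,6,0.137,1.24,0.9,1.6,5,5
fibrinogen,Fibrinogen >= 4.1 g/L,218,371,0.5,0.467,9,3.2,9,0.471,1.080,0.9,1.3,9,0.872,0.982,0.8,1.2,9,9
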