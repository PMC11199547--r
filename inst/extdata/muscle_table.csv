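name,group,side,origin_level,origin_ap,origin_si,insertion_level,insertion_ap,insertion_si,pcsa_m2
mf_l1_l,MF,L,pelvis,-0.047,-0.04,L1,-0.044,0,3.30e-04
mf_l2_l,MF,L,pelvis,-0.047,-0.04,L2,-0.044,0,3.30e-04
mf_l3_l,MF,L,pelvis,-0.047,-0.04,L3,-0.044,0,3.30e-04
mf_l4_l,MF,L,pelvis,-0.047,-0.04,L4,-0.044,0,3.30e-04
mf_l5_l,MF,L,pelvis,-0.047,-0.04,L5,-0.044,0,3.30e-04
ltl_l1_l,LTL,L,pelvis,-0.046,-0.045,L1,-0.046,0,2.00e-04
ltl_l2_l,LTL,L,pelvis,-0.046,-0.045,L2,-0.046,0,2.00e-04
ltl_l3_l,LTL,L,pelvis,-0.046,-0.045,L3,-0.046,0,2.00e-04
ltl_l4_l,LTL,L,pelvis,-0.046,-0.045,L4,-0.046,0,2.00e-04
ltl_l5_l,LTL,L,pelvis,-0.046,-0.045,L5,-0.046,0,2.00e-04
il_t11_l,IL,L,pelvis,-0.048,-0.05,T11,-0.044,0,6.00e-04
il_t12_l,IL,L,pelvis,-0.048,-0.05,T12,-0.044,0,6.00e-04
is_l5s_l,IS,L,pelvis,-0.045,-0.01,L5,-0.045,0,1.20e-04
is_l4l5_l,IS,L,L5,-0.045,0,L4,-0.045,0,1.20e-04
is_l3l4_l,IS,L,L4,-0.045,0,L3,-0.045,0,1.20e-04
is_l2l3_l,IS,L,L3,-0.045,0,L2,-0.045,0,1.20e-04
is_l1l2_l,IS,L,L2,-0.045,0,L1,-0.045,0,1.20e-04
is_t12l1_l,IS,L,L1,-0.045,0,T12,-0.045,0,1.20e-04
pm_l1_l,PM,L,L1,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l2_l,PM,L,L2,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l3_l,PM,L,L3,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l4_l,PM,L,L4,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l5_l,PM,L,L5,0.035,0,pelvis,0.02,-0.1,3.00e-04
ql_l,QL,L,pelvis,-0.027,-0.03,T12,-0.025,0,3.00e-04
ra_l,RA,L,pelvis,0.09,-0.06,T9,0.1,0,6.00e-04
eo_l,EO,L,pelvis,0.055,-0.03,T10,0.08,0,8.00e-04
io_l,IO,L,pelvis,0.05,-0.02,T12,0.07,0,8.00e-04
mf_l1_r,MF,R,pelvis,-0.047,-0.04,L1,-0.044,0,3.30e-04
mf_l2_r,MF,R,pelvis,-0.047,-0.04,L2,-0.044,0,3.30e-04
mf_l3_r,MF,R,pelvis,-0.047,-0.04,L3,-0.044,0,3.30e-04
mf_l4_r,MF,R,pelvis,-0.047,-0.04,L4,-0.044,0,3.30e-04
mf_l5_r,MF,R,pelvis,-0.047,-0.04,L5,-0.044,0,3.30e-04
ltl_l1_r,LTL,R,pelvis,-0.046,-0.045,L1,-0.046,0,2.00e-04
ltl_l2_r,LTL,R,pelvis,-0.046,-0.045,L2,-0.046,0,2.00e-04
ltl_l3_r,LTL,R,pelvis,-0.046,-0.045,L3,-0.046,0,2.00e-04
ltl_l4_r,LTL,R,pelvis,-0.046,-0.045,L4,-0.046,0,2.00e-04
ltl_l5_r,LTL,R,pelvis,-0.046,-0.045,L5,-0.046,0,2.00e-04
il_t11_r,IL,R,pelvis,-0.048,-0.05,T11,-0.044,0,6.00e-04
il_t12_r,IL,R,pelvis,-0.048,-0.05,T12,-0.044,0,6.00e-04
is_l5s_r,IS,R,pelvis,-0.045,-0.01,L5,-0.045,0,1.20e-04
is_l4l5_r,IS,R,L5,-0.045,0,L4,-0.045,0,1.20e-04
is_l3l4_r,IS,R,L4,-0.045,0,L3,-0.045,0,1.20e-04
is_l2l3_r,IS,R,L3,-0.045,0,L2,-0.045,0,1.20e-04
is_l1l2_r,IS,R,L2,-0.045,0,L1,-0.045,0,1.20e-04
is_t12l1_r,IS,R,L1,-0.045,0,T12,-0.045,0,1.20e-04
pm_l1_r,PM,R,L1,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l2_r,PM,R,L2,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l3_r,PM,R,L3,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l4_r,PM,R,L4,0.035,0,pelvis,0.02,-0.1,3.00e-04
pm_l5_r,PM,R,L5,0.035,0,pelvis,0.02,-0.1,3.00e-04
ql_r,QL,R,pelvis,-0.027,-0.03,T12,-0.025,0,3.00e-04
ra_r,RA,R,pelvis,0.09,-0.06,T9,0.1,0,6.00e-04
eo_r,EO,R,pelvis,0.055,-0.03,T10,0.08,0,8.00e-04
io_r,IO,R,pelvis,0.05,-0.02,T12,0.07,0,8.00e-04
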