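model,description,iiv_on,npar,ofv,aic,aic_consistent
A1,One-compartment model with first-order absorption (combined error),CL V1 Ka,8,5833.20,5849.20,TRUE
A2,Two-compartment model with first-order absorption,CL V1 Ka,9,5744.65,5764.65,FALSE
A3,Three-compartment model with first-order absorption,CL V1 Ka,11,5744.52,5766.52,TRUE
B1,Two-compartment model with first-order absorption and lag time,CL V1 Ka,10,5598.49,5618.49,TRUE
B2,Two-compartment model with zero-order absorption and lag time,CL V1 D,10,5551.73,5571.73,TRUE
B3,Two-compartment double-peak model (two Ka and two lag times),CL V1 Ka1,14,5406.26,5582.43,FALSE
B4,Two-compartment transit model,CL V1 Ka,11,5570.73,5592.73,TRUE
C1,Two-compartment model with first-order absorption and lag time,CL V1 Ka ALAG,11,5458.12,5480.12,TRUE
C2,Two-compartment model with zero-order absorption and lag time,CL V1 D ALAG,11,5365.24,5387.24,TRUE
C3,Two-compartment double-peak model (two Ka and two lag times),CL V1 Ka1 ALAG1,14,5417.70,5445.70,TRUE
C4,Two-compartment double-peak model (one Ka and two lag times),CL V1 Ka ALAG1,13,5408.64,5434.64,TRUE
C5,Two-compartment transit model,CL V1 Ka MTT,12,5344.57,5368.57,TRUE
D1,Two-compartment transit model with correlated CL-V1 random effects,CL V1 Ka MTT,13,5300.04,5326.04,TRUE
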