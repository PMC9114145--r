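"name","Fmax","lopt","lslack","w","ndof","dof1","r1","thmax1","thref1","sgn1","dof2","r2","thmax2","thref2","sgn2","leg","vmax","fvN","fvK","epsref","tauA"
"HFL_L",2000,0.15,0.1,0.8,1,0,0.08,NA,0.7,1,-1,0,NA,0,1,0,1.8,1.5,5,0.04,0.01
"GLU_L",1500,0.15,0.13,0.8,1,0,0.08,NA,0.7,-1,-1,0,NA,0,1,0,1.8,1.5,5,0.04,0.01
"HAM_L",3000,0.18,0.3,1,2,0,0.07,NA,0.7,-1,2,0.04,NA,1.31,1,0,2.16,1.5,5,0.04,0.01
"RF_L",1200,0.16,0.34,1,2,0,0.05,NA,0.7,1,2,0.05,0.8,1.31,-1,0,1.92,1.5,5,0.04,0.01
"VAS_L",6000,0.11,0.23,0.7,1,2,0.055,0.8,1.31,-1,-1,0,NA,0,1,0,1.32,1.5,5,0.04,0.01
"BFSH_L",800,0.11,0.16,0.7,1,2,0.04,NA,1.31,1,-1,0,NA,0,1,0,1.32,1.5,5,0.04,0.01
"GAS_L",1500,0.12,0.38,1,2,2,0.015,NA,1.31,1,3,0.05,-0.2,-0.1,-1,0,1.44,1.5,5,0.04,0.01
"SOL_L",4000,0.08,0.25,0.65,1,3,0.05,-0.2,-0.1,-1,-1,0,NA,0,1,0,0.96,1.5,5,0.04,0.01
"TA_L",1200,0.07,0.22,0.6,1,3,0.04,0.2,-0.1,1,-1,0,NA,0,1,0,0.84,1.5,5,0.04,0.01
"HAB_L",3000,0.08,0.07,0.5,1,1,0.06,NA,0,-1,-1,0,NA,0,1,0,0.96,1.5,5,0.04,0.01
"HAD_L",4500,0.08,0.12,0.4,1,1,0.04,NA,0,1,-1,0,NA,0,1,0,0.96,1.5,5,0.04,0.01
"HFL_R",2000,0.15,0.1,0.8,1,0,0.08,NA,0.7,1,-1,0,NA,0,1,1,1.8,1.5,5,0.04,0.01
"GLU_R",1500,0.15,0.13,0.8,1,0,0.08,NA,0.7,-1,-1,0,NA,0,1,1,1.8,1.5,5,0.04,0.01
"HAM_R",3000,0.18,0.3,1,2,0,0.07,NA,0.7,-1,2,0.04,NA,1.31,1,1,2.16,1.5,5,0.04,0.01
"RF_R",1200,0.16,0.34,1,2,0,0.05,NA,0.7,1,2,0.05,0.8,1.31,-1,1,1.92,1.5,5,0.04,0.01
"VAS_R",6000,0.11,0.23,0.7,1,2,0.055,0.8,1.31,-1,-1,0,NA,0,1,1,1.32,1.5,5,0.04,0.01
"BFSH_R",800,0.11,0.16,0.7,1,2,0.04,NA,1.31,1,-1,0,NA,0,1,1,1.32,1.5,5,0.04,0.01
"GAS_R",1500,0.12,0.38,1,2,2,0.015,NA,1.31,1,3,0.05,-0.2,-0.1,-1,1,1.44,1.5,5,0.04,0.01
"SOL_R",4000,0.08,0.25,0.65,1,3,0.05,-0.2,-0.1,-1,-1,0,NA,0,1,1,0.96,1.5,5,0.04,0.01
"TA_R",1200,0.07,0.22,0.6,1,3,0.04,0.2,-0.1,1,-1,0,NA,0,1,1,0.84,1.5,5,0.04,0.01
"HAB_R",3000,0.08,0.07,0.5,1,1,0.06,NA,0,-1,-1,0,NA,0,1,1,0.96,1.5,5,0.04,0.01
"HAD_R",4500,0.08,0.12,0.4,1,1,0.04,NA,0,1,-1,0,NA,0,1,1,0.96,1.5,5,0.04,0.01
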