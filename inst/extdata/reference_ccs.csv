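# Experimental and Boltzmann-weighted computed CCS values (A^2) for 23
# singly protonated [M + H]+ tryptic peptide ions in N2 drift gas.
# Experimental values: drift-tube IM-MS (Unified CCS Compendium lineage).
# Computed columns: trajectory-method CCS of DFT equilibrium structures at
# B3LYP/6-31G(d) (uncorrected and with D3(0)/D3(BJ) dispersion) and at
# B3LYP/6-31G(d,p) (D3(0)/D3(BJ)).  Version 1; values as published.
peptide,exp_ccs,b3lyp_631gd,d3_0_631gd,d3_bj_631gd,d3_0_631gdp,d3_bj_631gdp
ANELLINVK,322.50,347.62,322.93,342.93,335.91,332.21
AWEVTVK,278.20,333.91,295.78,296.11,286.04,294.42
AWSVAR,255.70,290.00,264.29,274.98,274.57,265.11
DYYFALAHTVR,374.80,410.42,412.60,422.64,389.49,392.12
ELR,200.30,197.81,203.43,201.62,207.93,199.88
EWTR,229.70,250.20,241.93,243.40,237.44,237.03
EYK,203.20,213.81,210.64,209.78,209.74,209.02
FAAYLER,293.10,335.07,302.10,307.17,292.77,287.53
FLNR,231.60,250.13,231.08,238.48,237.89,237.60
FPK,184.70,193.09,188.53,188.59,188.09,187.84
FSSDR,234.50,250.05,250.86,240.25,241.62,241.31
GLVK,205.30,210.80,210.69,210.63,208.71,211.01
LWSAK,237.70,267.85,243.40,243.63,236.19,250.71
NFNR,224.00,252.51,247.61,239.92,219.20,217.09
NIATGSK,255.30,298.74,257.95,248.67,260.08,253.95
poly-6-glycine,171.04,176.67,174.29,170.03,172.39,175.29
poly-8-glycine,206.52,203.34,201.43,197.56,197.76,197.50
poly-10-glycine,216.15,232.7,222.58,222.02,225.89,219.44
poly-14-glycine,254.51,277.82,266.42,266.33,264.76,263.74
TFAEALR,281.80,339.29,304.43,295.93,295.01,290.69
TIAQYAR,280.00,315.95,282.10,300.94,280.33,277.79
VASLR,232.00,230.65,223.39,232.05,228.70,228.3
WIR,213.20,210.41,217.68,208.50,205.63,210.41
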