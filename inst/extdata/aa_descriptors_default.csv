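aa,hydropathy_kd,hydrophilicity_hw,residue_mass,volume_a3,charge_ph7,isoelectric_point,polarity_grantham,helix_cf,sheet_cf,turn_cf,flexibility_bp,bulkiness_zim,refractivity,asa_tripeptide,side_heavy_atoms,hbond_donors,hbond_acceptors,aromatic
A,1.8,-0.5,71.08,88.6,0,6.00,8.1,1.42,0.83,0.66,0.357,11.50,4.34,115,1,0,0,0
C,2.5,-1.0,103.14,108.5,0,5.07,5.5,0.70,1.19,1.19,0.346,13.46,35.77,135,2,1,1,0
D,-3.5,3.0,115.09,111.1,-1,2.77,13.0,1.01,0.54,1.46,0.511,11.68,12.00,150,4,0,4,0
E,-3.5,3.0,129.12,138.4,-1,3.22,12.3,1.51,0.37,0.74,0.497,13.57,17.26,190,5,0,4,0
F,2.8,-2.5,147.18,189.9,0,5.48,5.2,1.13,1.38,0.60,0.314,19.80,29.40,210,7,0,0,1
G,-0.4,0.0,57.05,60.1,0,5.97,9.0,0.57,0.75,1.56,0.544,3.40,0.00,75,0,0,0,0
H,-3.2,-0.5,137.14,153.2,0.1,7.59,10.4,1.00,0.87,0.95,0.323,13.69,21.81,195,6,1,1,1
I,4.5,-1.8,113.16,166.7,0,6.02,5.2,1.08,1.60,0.47,0.462,21.40,19.06,175,4,0,0,0
K,-3.9,3.0,128.17,168.6,1,9.74,11.3,1.16,0.74,1.01,0.466,15.71,21.29,200,5,3,0,0
L,3.8,-1.8,113.16,166.7,0,5.98,4.9,1.21,1.30,0.59,0.365,21.40,18.78,170,4,0,0,0
M,1.9,-1.3,131.19,162.9,0,5.74,5.7,1.45,1.05,0.60,0.295,16.25,21.64,185,4,0,1,0
N,-3.5,0.2,114.10,114.1,0,5.41,11.6,0.67,0.89,1.56,0.463,12.82,13.28,160,4,2,2,0
P,-1.6,0.0,97.12,112.7,0,6.30,8.0,0.57,0.55,1.52,0.509,17.43,10.93,145,3,0,0,0
Q,-3.5,0.2,128.13,143.8,0,5.65,10.5,1.11,1.10,0.98,0.493,14.45,17.56,180,5,2,2,0
R,-4.5,3.0,156.19,173.4,1,10.76,10.5,0.98,0.93,0.95,0.529,14.28,26.66,225,7,5,1,0
S,-0.8,0.3,87.08,89.0,0,5.68,9.2,0.77,0.75,1.43,0.507,9.47,6.35,115,2,1,1,0
T,-0.7,-0.4,101.10,116.1,0,5.60,8.6,0.83,1.19,0.96,0.444,15.77,11.01,140,3,1,1,0
V,4.2,-1.5,99.13,140.0,0,5.96,5.9,1.06,1.70,0.50,0.386,21.57,13.92,155,3,0,0,0
W,-0.9,-3.4,186.21,227.8,0,5.89,5.4,1.08,1.37,0.96,0.305,21.67,42.53,255,10,1,0,1
Y,-1.3,-2.3,163.18,193.6,0,5.66,6.2,0.69,1.47,1.14,0.420,18.03,31.53,230,8,1,1,1
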