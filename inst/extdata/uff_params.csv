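element,D_kcal_mol,x_angstrom,source
H,0.044,2.886,rdkit-uff
He,0.056,2.362,uff-publication
Li,0.025,2.451,rdkit-uff
Be,0.085,2.745,rdkit-uff
B,0.18,4.083,rdkit-uff
C,0.105,3.851,rdkit-uff
N,0.069,3.66,rdkit-uff
O,0.06,3.5,rdkit-uff
F,0.05,3.364,rdkit-uff
Ne,0.042,3.243,uff-publication
Na,0.03,2.983,rdkit-uff
Mg,0.111,3.021,rdkit-uff
Al,0.505,4.499,rdkit-uff
Si,0.402,4.295,rdkit-uff
P,0.305,4.147,rdkit-uff
S,0.274,4.035,rdkit-uff
Cl,0.227,3.947,rdkit-uff
Ar,0.185,3.868,uff-publication
K,0.035,3.812,rdkit-uff
Ca,0.238,3.399,uff-publication
Sc,0.019,3.295,rdkit-uff
Ti,0.017,3.175,rdkit-uff
V,0.016,3.144,rdkit-uff
Cr,0.015,3.023,uff-publication
Mn,0.013,2.961,uff-publication
Fe,0.013,2.912,rdkit-uff
Co,0.014,2.872,rdkit-uff
Ni,0.015,2.834,uff-publication
Cu,0.005,3.495,rdkit-uff
Zn,0.124,2.763,uff-publication
Ga,0.415,4.383,rdkit-uff
Ge,0.379,4.28,rdkit-uff
As,0.309,4.23,rdkit-uff
Se,0.291,4.205,rdkit-uff
Br,0.251,4.189,rdkit-uff
Kr,0.22,4.141,uff-publication
Rb,0.04,4.114,rdkit-uff
Sr,0.235,3.641,uff-publication
Y,0.072,3.345,uff-publication
Zr,0.069,3.124,uff-publication
Nb,0.059,3.165,rdkit-uff
Mo,0.056,3.052,rdkit-uff
Tc,0.048,2.998,rdkit-uff
Ru,0.056,2.963,uff-publication
Rh,0.053,2.929,uff-publication
Pd,0.048,2.899,uff-publication
Ag,0.036,3.148,uff-publication
Cd,0.228,2.848,uff-publication
In,0.599,4.463,rdkit-uff
Sn,0.567,4.392,rdkit-uff
Sb,0.449,4.42,rdkit-uff
Te,0.398,4.47,rdkit-uff
I,0.339,4.5,rdkit-uff
Xe,0.332,4.404,uff-publication
Cs,0.045,4.517,rdkit-uff
Ba,0.364,3.703,uff-publication
La,0.017,3.522,rdkit-uff
Ce,0.013,3.168,uff-publication
Pr,0.01,3.212,uff-publication
Nd,0.01,3.185,uff-publication
Pm,0.009,3.16,uff-publication
Sm,0.008,3.136,uff-publication
Eu,0.008,3.112,uff-publication
Gd,0.009,3.368,rdkit-uff
Tb,0.007,3.451,rdkit-uff
Dy,0.007,3.428,rdkit-uff
Ho,0.007,3.409,rdkit-uff
Er,0.007,3.391,rdkit-uff
Tm,0.006,3.374,rdkit-uff
Yb,0.228,3.355,rdkit-uff
Lu,0.041,3.64,rdkit-uff
Hf,0.072,3.141,uff-publication
Ta,0.081,3.17,rdkit-uff
W,0.067,3.069,uff-publication
Re,0.066,2.954,rdkit-uff
Os,0.037,3.12,uff-publication
Ir,0.073,2.84,uff-publication
Pt,0.08,2.754,uff-publication
Au,0.039,3.293,uff-publication
Hg,0.385,2.705,rdkit-uff
Tl,0.68,4.347,rdkit-uff
Pb,0.663,4.297,uff-publication
Bi,0.518,4.37,rdkit-uff
Po,0.325,4.709,rdkit-uff
At,0.284,4.75,rdkit-uff
Rn,0.248,4.245,uff-publication
Fr,0.05,4.9,rdkit-uff
Ra,0.404,3.677,uff-publication
Ac,0.033,3.478,uff-publication
Th,0.026,3.396,uff-publication
Pa,0.022,3.424,uff-publication
U,0.022,3.395,uff-publication
Np,0.019,3.424,uff-publication
Pu,0.016,3.424,uff-publication
Am,0.014,3.381,uff-publication
Cm,0.013,3.326,uff-publication
Bk,0.013,3.339,uff-publication
Cf,0.013,3.313,uff-publication
Es,0.012,3.299,uff-publication
Fm,0.012,3.286,uff-publication
Md,0.011,3.274,uff-publication
No,0.011,3.248,uff-publication
Lr,0.011,3.236,uff-publication
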