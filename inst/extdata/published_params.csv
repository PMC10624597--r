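name,units,floating,origin,HEK-hERG1,PANC-1,HCT116
k_c,s^-1,TRUE,published,0.402,1.43,1.5
k_g,s^-1,TRUE,published,0.0524,0.139,0.205
k_tg,s^-1,TRUE,published,0.00304,0.00206,0.00154
k_e,(#/cell)^-1 s^-1,TRUE,published,3.55e-5,0.000227,0.000352
k_te,s^-1,TRUE,published,0.0608,0.0218,0.0292
k_de,s^-1,TRUE,published,0.105,0.18,0.253
k_off,s^-1,TRUE,published,107,346,234
k_on,(#/cell)^-1 s^-1,TRUE,published,4.24e-5,0.000113,8.82e-5
k_mf,s^-1,TRUE,published,8.05e-6,8.37e-5,8.79e-5
k_a,(#/cell)^-1 s^-1,TRUE,published,4.91e-8,1.18e-7,1.92e-7
k_am,(#/cell)^-2 s^-1,TRUE,published,0.000258,0.000873,0.000486
k_i,(#/cell)^-1 s^-1,TRUE,published,1.23e-9,1.17e-9,1.73e-9
k_ie,(#/cell)^-1 s^-1,TRUE,published,65.2,79.2,71.8
k_n,(#/cell)^-1 s^-1,TRUE,published,163,100,86.4
k_np,s^-1,TRUE,published,0.000776,0.000898,0.00109
k_mn,s^-1,TRUE,published,0.0134,0.01,0.0116
k_cp,(#/cell)^-1 s^-1,TRUE,published,0.00804,0.0286,0.03
k_gp,(#/cell)^-1 s^-1,TRUE,published,0.000698,0.00185,0.00274
k_tgp,(#/cell)^-1 s^-1,TRUE,published,0.000108,7.32e-5,5.46e-5
k_dm,s^-1,TRUE,published,0.105,0.18,0.253
kf0,(#/cell)^-1 s^-1,TRUE,published,1.75e-5,6.29e-6,8.42e-6
k_iep,s^-1,TRUE,published,0.132,0.225,0.317
k_om,s^-1,FALSE,published,8,8,8
k_o,s^-1,FALSE,published,0.15,0.15,0.15
B0,#/cell,FALSE,published,1.709e7,1.709e7,1.709e7
A0,#/cell,FALSE,published,1500,1500,1500
I0,#/cell,FALSE,published,1500,1500,1500
E0,#/cell,FALSE,published,1000,1000,1000
F0,#/cell,FALSE,published,240000,240000,240000
g_dose,#/cell,FALSE,reconstruction,1,1,1
N0,#/cell,FALSE,reconstruction,1000,1000,1000
phi0,dimensionless,FALSE,reconstruction,0.4,0.4,0.4
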