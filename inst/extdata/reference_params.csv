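name,units,floating,origin,HEK-hERG1
k_c,s^-1,TRUE,calibrated,3.34e-05
k_g,s^-1,TRUE,calibrated,0.005643
k_tg,s^-1,TRUE,calibrated,0.0008
k_e,(#/cell)^-1 s^-1,TRUE,calibrated,0.0002162
k_te,s^-1,TRUE,calibrated,0.008286
k_de,s^-1,TRUE,calibrated,0.03804
k_off,s^-1,TRUE,calibrated,0.0003233
k_on,(#/cell)^-1 s^-1,TRUE,calibrated,5.901e-10
k_mf,s^-1,TRUE,calibrated,1.849e-06
k_a,(#/cell)^-1 s^-1,TRUE,calibrated,9.311e-08
k_am,(#/cell)^-2 s^-1,TRUE,calibrated,7.082e-07
k_i,(#/cell)^-1 s^-1,TRUE,calibrated,4.336e-10
k_ie,(#/cell)^-1 s^-1,TRUE,calibrated,0.0002347
k_n,(#/cell)^-1 s^-1,TRUE,calibrated,0.001456
k_np,s^-1,TRUE,calibrated,0.0007957
k_mn,s^-1,TRUE,calibrated,0.0004083
k_cp,(#/cell)^-1 s^-1,TRUE,calibrated,0.000187
k_gp,(#/cell)^-1 s^-1,TRUE,calibrated,0.000103
k_tgp,(#/cell)^-1 s^-1,TRUE,calibrated,1e-09
k_dm,s^-1,TRUE,calibrated,0.0003151
kf0,(#/cell)^-1 s^-1,TRUE,calibrated,1.279e-10
k_iep,s^-1,TRUE,calibrated,8.63e-05
k_om,s^-1,FALSE,published,8
k_o,s^-1,FALSE,published,0.15
B0,#/cell,FALSE,published,1.709e7
A0,#/cell,FALSE,published,1500
I0,#/cell,FALSE,published,1500
E0,#/cell,FALSE,published,1000
F0,#/cell,FALSE,published,240000
g_dose,#/cell,FALSE,reconstruction,1
N0,#/cell,FALSE,reconstruction,1000
phi0,dimensionless,FALSE,reconstruction,0.4
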