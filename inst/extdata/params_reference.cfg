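# Synthetic reference parameter table of the copdnet immune-network model.
# Calibrated to the model's qualitative regime structure; not transcribed
# from any published table. Units per key are noted inline.
k1 = 0.016625000000000001  # cell/(ml day)
k2 = 0.0099799999999999993  # cell/(ml day)
k3 =             0.1575  # cell/(ml day)
k4 =              0.039  # cell/(ml day)
k5 =           0.015091  # cell/(ml day)
k6 =               0.02  # cell/(ml day)
k7 = 0.0011000000000000001  # cell/(ml day)
k8 =             0.0014  # cell/(ml day)
k9 = 0.0016999999999999999  # cell/(ml day)
k10 =             0.0015  # cell/(ml day)
k11 =             0.0201  # cell/(ml day)
k12 =          0.0001108  # 1/day
k13 =             0.0115  # ml/(cell day)
k14 = 0.0064999999999999997  # ml/(cell day)
k15 = 0.00089999999999999998  # 1/day
kp1 =               0.01  # 1/day
kp2 =               0.01  # 1/day
kp8 = 0.021999999999999999  # 1/day
kp17 = 0.021999999999999999  # 1/day
kgp = 0.0071999999999999998  # cell/(ml day)
kI4_T2 =                 25  # pmol ml/(L cell day)
kI4_TD =                  4  # pmol/(L day)
kI6_M1 =                300  # pmol ml/(L cell day)
kI6_TD = 5.5999999999999996  # pmol/(L day)
kI10_M2 =                110  # pmol ml/(L cell day)
kI10_Tg =                609  # pmol ml/(L cell day)
kI12_M1 =                 45  # pmol ml/(L cell day)
kI17_T17 =                146  # pmol ml/(L cell day)
kI21_T17 =                109  # pmol ml/(L cell day)
kIa_M1 =                151  # pmol ml/(L cell day)
kIg_T1 =                104  # pmol ml/(L cell day)
kIg_T8 =               62.5  # pmol ml/(L cell day)
kIb_M2 =                 60  # pmol ml/(L cell day)
K1 =                  8  # pmol/L
K2 =                  5  # pmol/L
K3 =                  5  # pmol/L
K4 =                 10  # pmol/L
K5 =                 10  # pmol/L
K6 =                1.5  # pmol/L
K7 =                 12  # pmol/L
K8 =                 10  # pmol/L
K9 =                 10  # pmol/L
K10 =                 12  # pmol/L
K11 =                 12  # pmol/L
K12 =                 12  # pmol/L
K_TD_Ig =                  6  # pmol/L
K_TD_I17 =                  6  # pmol/L
K_TD_I10 =                 12  # pmol/L
K_TD_Ib =                  6  # pmol/L
KT1 =                  1  # pmol/L
KT2 = 0.40000000000000002  # pmol/L
KT8 =                  1  # pmol/L
KT1_10 =                 12  # pmol/L
KT2_10 =                 20  # pmol/L
KT8_10 =                 12  # pmol/L
KT17_10 =                 12  # pmol/L
KT1_I10p =                 12  # pmol/L
KT2_I10p =                 20  # pmol/L
KT8_I10p =                 30  # pmol/L
KT17_I10p =                 30  # pmol/L
K_T17_I6 =                  7  # (pmol/L)^2
K_Tg =                2.5  # pmol/L
K_Tg_I6 = 5.7999999999999998  # pmol/L
K_pTg_I10 =                  4  # pmol/L
K_M1_I10 =                 15  # pmol/L
K_M2_I10 =                 20  # pmol/L
K_T1_I10 =                 12  # pmol/L
K_T2_I10 =                 20  # pmol/L
K_T8_I10 =                 12  # pmol/L
K_T17_I10 =                 12  # pmol/L
K_I4_I10 =                 12  # pmol/L
K_I6_I10 =                 12  # pmol/L
K_I10_I10 =                 10  # pmol/L
d_M1 = 0.20999999999999999  # 1/day
d_M2 = 0.20000000000000001  # 1/day
d_DC = 0.29999999999999999  # 1/day
d_T1 = 0.029999999999999999  # 1/day
d_T2 = 0.029999999999999999  # 1/day
d_T8 = 0.029999999999999999  # 1/day
d_T17 = 0.029999999999999999  # 1/day
d_Tg = 0.14999999999999999  # 1/day
d_I4 =                  2  # 1/day
d_I6 =                  2  # 1/day
d_I10 =                  1  # 1/day
d_I12 =                  2  # 1/day
d_I17 =                  2  # 1/day
d_I21 =                  2  # 1/day
d_Ia =                  2  # 1/day
d_Ig =                  2  # 1/day
d_Ib =                  2  # 1/day
d_TD = 0.0028999999999999998  # 1/day
n =                  2  # dimensionless
tg_prolif_mode =                  0  # flag
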