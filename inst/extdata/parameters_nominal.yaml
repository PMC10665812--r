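# Nominal parameter set: fasting-state obesity/T2D progression model.
# Time unit is months. Values calibrated to the baseline healthy state
# (BMI 25, beta 1000 mg) and the reference intervention behaviour.
k_w: 0.0026341200000000002  # kg per (kcal/day) per month; weight gained per unit daily intake
DE_i_b:               2500  # kcal/day; baseline daily energy intake
DE_e: 0.081299999999999997  # 1/month; energy-expenditure weight-loss rate (balance: k_w*DE_i_b = DE_e*25*h^2)
h:                1.8  # m; height of the reference individual
E_G0:                 40  # 1/month; insulin-independent glucose uptake (glucose effectiveness)
HGP_b:               4200  # mg/dL/month; non-suppressible hepatic glucose production
HGP_max:               9000  # mg/dL/month; insulin-suppressible hepatic glucose production
alpha_HGP:                220  # (S_i*I units); half-suppression constant of HGP
k_I:                100  # 1/month; insulin clearance rate
V: 0.23599999999999999  # distribution volume scale for insulin (absorbs secretion units)
alpha_ISR:               0.25  # half-max of ISR sigmoid in M
K_ISR:                  2  # Hill exponent of ISR sigmoid
alpha_M:                140  # mg/dL; half-max of metabolic-rate sigmoid in G
K_M:                  4  # Hill exponent of M sigmoid
K_siF:                120  # (S_i*I units); half-max of insulin suppression of lipolysis
alpha_SiF:                  2  # Hill exponent of lipolysis suppression
c_f: 0.20599999999999999  # 1/kg/month; FFA turnover per kg body weight
F_Ra0:               3000  # micromol/L/month; maximal lipolysis at zero fat mass
F_Ra1:                300  # micromol/L/month/kg; maximal lipolysis slope vs fat mass
FMR_a:              0.012  # 1/(kg/m2); fat-mass-ratio slope vs BMI
FMR_b: -0.029999999999999999  # fat-mass-ratio intercept
tau_theta:                  4  # months; inflammation time constant
n_theta:                 10  # Hill exponent of inflammation response to BMI
K_theta:                 40  # kg/m2; BMI of half-maximal inflammation
tau_Si:                  2  # months; insulin-sensitivity time constant
S_i_b:                 10  # insulin sensitivity scale (per microU/mL per month)
M_FFA: 0.90000000000000002  # fractional maximal reduction of S_i by FFA (0-1)
n_Si:                  3  # Hill exponent of FFA effect on S_i
K_Si_FFA:                500  # micromol/L; half-max of FFA effect on S_i
K_Si_theta:               0.75  # half-max of inflammation effect on S_i
P_ng:                 20  # mg/month (pre tau_beta); beta-cell neogenesis
P_max: 0.29999999999999999  # 1/month (pre tau_beta); maximal replication rate
n_P:                  3  # Hill exponent of replication vs ISR
alpha_P: 0.40000000000000002  # half-max ISR for replication
A_b: 0.029999999999999999  # 1/month (pre tau_beta); basal apoptosis
A_max: 0.20000000000000001  # 1/month (pre tau_beta); maximal workload-driven apoptosis
n_A:                  6  # Hill exponent of apoptosis vs M
alpha_A: 0.41999999999999998  # half-max M for apoptosis
s:    5.891959967e-05  # 1/mg/month (pre tau_beta); pairwise beta-cell interaction
tau_beta:                 15  # months; beta-cell mass timescale
tau_sigma:                  3  # months; beta-cell function time constant
sigma_b:                  1  # baseline scale of sigma_infinity
s_gu_max: 4.6190033860000002  # amplitude of glucose-driven sigma up-regulation (solved so bracket = 1 at baseline)
K_gu:                300  # mg/dL; half-max of sigma up-regulation
n_gu:                  1  # Hill exponent of sigma up-regulation
K_gd:                130  # mg/dL; half-max of glucotoxic component
n_gd:                  6  # Hill exponent of glucotoxicity
s_ffa_max: 2.4500000000000002  # amplitude of lipotoxic component
K_sf:                500  # micromol/L; half-max of lipotoxicity
n_sf:                  4  # Hill exponent of lipotoxicity
s_th_max: 0.69999999999999996  # amplitude of inflammation component of sigma
K_st: 0.55000000000000004  # half-max inflammation for sigma
n_st:                  4  # Hill exponent
S_i_0: 6.9551785309999996  # baseline insulin sensitivity (disease-progression-index reference)
sigma_0:                  1  # baseline beta-cell function (DPI reference)
beta_0:               1000  # mg; baseline beta-cell mass (DPI reference)
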