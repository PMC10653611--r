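# phytocycle default parameter set
# Flat key = value dialect: one constant per line, '#' starts a comment.
# Units: time, volume and protein mass in arbitrary units; first-order rates
# in 1/time.  See the package vignette for the provenance of each value.

# volume growth (calibrated so cells double over one cycle)
r_gr = 0.00065

# CDKA:CYCD
r_ca = 0.01
d_ca = 0.01
d_ca_scf = 0.0
d_ca_apc = 0.5
kD_ca_krp = 0.01

# KRP
r_krp = 0.01
r_krp_myb4 = 0.01
d_krp = 0.01
d_krp_fbl17 = 1

# E2FA (sub-stoichiometric to RBR; see vignette)
r_e2fa = 0.006
d_e2fa = 0.01
kD_e2fa_rbr = 0.001
kat_e2fa = 0.001

# E2FB
r_e2fb = 0
r_e2fb_e2fa = 0.01
d_e2fb = 0.01

# RBR
r_rbr = 0.01
d_rbr = 0.01
kdp_ca = 0.25

# FBL17
r_fbl17 = 0
r_fbl17_e2fa = 0.1
d_fbl17 = 0.1

# CDKA/B:CYCB
r_cb = 0
r_cb_e2fb = 0.3
kI_myb3 = 10
kat_e2fb = 0.001
d_cb = 0.01
d_cb_apc = 0.1
kD_cb_smr = 0.001

# MYB3R3
r_myb3 = 0.01
d_myb3 = 0.01
kdp_cb = 0.125

# MYB3R4
r_myb4 = 0.01
r_myb4_myb4 = 0.11
kat_myb4 = 0.001
d_myb4 = 0.1
kdp_cb1 = 0.125

# SMR
r_smr = 0.01
d_smr = 0.01
d_smr_cdkb = 0.1
kdp_cb2 = 0.25

# SCF
r_scf = 0
r_scf_e2fb = 0.01
d_scf = 0.01

# APC
r_apc = 0
r_apc_myb4 = 0.01
d_apc = 0.01
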