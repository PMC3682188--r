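## Frozen fixture calibration constants.
##
## Per-pair site-membrane LJ epsilon per kcal/mol of desired adhesion well
## depth, from calibrate_site_membrane_eps() at the fixture lipid
## parameters (sigma0 = 0.77 nm, aspect 3:1, area per lipid 0.75 nm^2):
## a site with contact length sigma_pl approached to a flat fixture leaflet
## has an adhesion profile whose depth per unit per-pair epsilon is
## 5.4648 (sigma_pl = 1.16 nm, the H0 sites) and 4.1495 (sigma_pl = 1.00,
## the R114 loop site).  The equilibrium sits ~0.1-0.3 nm below the
## headgroup shell, i.e. shallow interfacial insertion.
PL_EPS_PER_WELL <- c(h0 = 1 / 5.46480302, r114 = 1 / 4.149463337)
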