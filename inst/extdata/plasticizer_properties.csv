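abbreviation,full_name,mw,p_vap_torr,s_w_mg_ml,log_kow,k_lip,k_pol,k_aq,loq_mg_kg,reference_dose,rfd_basis,property_source
DBP,dibutyl phthalate,278.34,2.0e-5,1.12e-2,4.50,,,,30.6,2,"LOAEL, endpoint: germ cell development, species: rat","PubChem CID 3026 (experimental, 25 C)"
DEHP,di(2-ethylhexyl) phthalate,390.56,1.4e-7,2.7e-4,7.60,,,,32.5,3,"NOAEL, endpoint: nipple retention, species: rat","PubChem CID 8343 (experimental, 25 C)"
DEP,diethyl phthalate,222.24,2.1e-3,1.08,2.42,,,,44.0,750,"NOAEL, endpoint: decreased growth rate, species: rat","PubChem CID 6781 (experimental, 25 C)"
DIBP,di-isobutyl phthalate,278.34,4.8e-5,6.2e-3,4.11,,,,33.1,125,"NOAEL, endpoint: nipple retention, species: rat","PubChem CID 6782 (experimental, 25 C)"
DINP,diisononyl phthalate,418.61,5.4e-7,6.1e-7,8.80,,,,35.6,15,"NOAEL, endpoint: hepatotoxicity, species: rat","PubChem CID 590836 (experimental, 25 C)"
DEHA,di(2-ethylhexyl) adipate,370.57,8.5e-7,7.8e-4,6.11,,,,41.0,170,"NOAEL, endpoint: changes in bodyweight and liver weight, species: rat","PubChem CID 7641 (experimental, 25 C)"
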