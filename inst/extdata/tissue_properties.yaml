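# Per-tissue dielectric and thermal properties at the discrete operating
# frequency set of the applicator (250, 375, 500 MHz).
#
# Dielectric values (relative permittivity eps_r and conductivity sigma, S/m)
# follow the IT'IS tissue database at these frequencies; tumor dielectrics are
# an average over malignant tissues. Tumor thermal properties: density
# 1090 kg/m3, specific heat 3421 J/kg/K, thermal conductivity 0.49 W/m/K.
# Perfusion is in ml/min/kg.
version: 1
frequencies_hz: [250.0e6, 375.0e6, 500.0e6]
tissues:
  water:
    eps_r:   [78.0, 78.0, 78.0]
    sigma:   [0.02, 0.03, 0.04]
    rho: 1000.0
    cp: 4178.0
    k_th: 0.60
    perfusion: 0.0
  skin:
    eps_r:   [46.8, 45.6, 44.9]
    sigma:   [0.64, 0.68, 0.73]
    rho: 1109.0
    cp: 3391.0
    k_th: 0.37
    perfusion: 106.0
  muscle:
    eps_r:   [56.9, 55.6, 54.9]
    sigma:   [0.73, 0.77, 0.82]
    rho: 1090.0
    cp: 3421.0
    k_th: 0.49
    perfusion: 37.0
  bone_cortical:
    eps_r:   [13.5, 12.9, 12.4]
    sigma:   [0.088, 0.10, 0.12]
    rho: 1908.0
    cp: 1313.0
    k_th: 0.32
    perfusion: 10.0
  csf:
    eps_r:   [70.9, 69.5, 68.4]
    sigma:   [2.26, 2.36, 2.46]
    rho: 1007.0
    cp: 4096.0
    k_th: 0.57
    perfusion: 0.0
  brain_gray:
    eps_r:   [56.5, 54.9, 53.9]
    sigma:   [0.80, 0.87, 0.94]
    rho: 1045.0
    cp: 3696.0
    k_th: 0.55
    perfusion: 763.0
  brain_white:
    eps_r:   [41.8, 40.4, 39.5]
    sigma:   [0.49, 0.54, 0.59]
    rho: 1041.0
    cp: 3583.0
    k_th: 0.51
    perfusion: 212.0
  eye:
    eps_r:   [69.1, 69.0, 68.9]
    sigma:   [1.52, 1.53, 1.55]
    rho: 1005.0
    cp: 4047.0
    k_th: 0.59
    perfusion: 0.0
  cartilage:
    eps_r:   [44.2, 43.1, 42.4]
    sigma:   [0.58, 0.63, 0.69]
    rho: 1100.0
    cp: 3568.0
    k_th: 0.49
    perfusion: 35.0
  pharynx_air:
    eps_r:   [1.0, 1.0, 1.0]
    sigma:   [0.0, 0.0, 0.0]
    rho: 1.2
    cp: 1004.0
    k_th: 0.026
    perfusion: 0.0
  tumor:
    eps_r:   [59.0, 57.5, 56.5]
    sigma:   [0.89, 0.96, 1.02]
    rho: 1090.0
    cp: 3421.0
    k_th: 0.49
    perfusion: 72.0
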