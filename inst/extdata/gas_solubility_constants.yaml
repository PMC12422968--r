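# Natural-log solubility fits of the form
#   ln y = A1 + A2*(100/T) + A3*ln(T/100) [+ A4*(T/100)]
#          + S * (B1 + B2*(T/100) + B3*(T/100)^2)
# with T in kelvin and S in practical salinity (ppt).
#
# Conventions:
#   bunsen      - y is the dimensionless Bunsen coefficient (volume of gas at
#                 STP absorbed per volume of solution at 1 atm partial
#                 pressure); Yamamoto/Wiesenburg-Guinasso lineage fit.
#   nmol_per_l  - y is the atmospheric equilibrium concentration in nmol L^-1
#                 for a dry-air mole fraction f_G (moist atmosphere at 1 atm
#                 total pressure folded into the fit); requires A4.
ch4:
  bunsen:
    A1: -67.1962
    A2: 99.1624
    A3: 27.9015
    B1: -0.072909
    B2: 0.041674
    B3: -0.0064603
  nmol_per_l:
    A1: -415.2807
    A2: 596.8104
    A3: 379.2599
    A4: -62.0757
    B1: -0.059160
    B2: 0.032174
    B3: -0.0048198
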