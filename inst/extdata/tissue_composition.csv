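# Tissue composition table for composition-based partition coefficients.
# Fractions are volume fractions; protein is the albumin-equivalent binding
# fraction referenced to plasma albumin. pH is intracellular-weighted tissue pH.
# Literature-style values (reference-human compilations); version: 1
organ,f_water,f_neutral_lipid,f_phospholipid,f_protein,pH
plasma,0.945,0,0,0.042,7.40
adipose,0.18,0.79,0.002,0.010,7.10
bone,0.42,0.07,0.001,0.030,7.00
brain,0.77,0.05,0.055,0.040,7.10
gut_wall,0.76,0.05,0.017,0.060,7.00
heart,0.73,0.014,0.012,0.060,7.10
kidney,0.78,0.012,0.024,0.050,7.22
liver,0.73,0.014,0.024,0.090,7.23
lung,0.82,0.022,0.013,0.040,7.00
muscle,0.76,0.022,0.008,0.050,7.00
pancreas,0.66,0.040,0.017,0.060,7.10
skin,0.72,0.060,0.011,0.070,7.00
spleen,0.78,0.011,0.013,0.050,7.10
stomach,0.75,0.032,0.017,0.060,7.00
gonads,0.80,0.017,0.013,0.050,7.10
uterus,0.79,0.014,0.012,0.050,7.10
placenta,0.84,0.011,0.012,0.050,7.20
mammary,0.50,0.45,0.008,0.040,7.10
fetus,0.83,0.012,0.010,0.040,7.10
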