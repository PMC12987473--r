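treatment,single_fruit_weight_kg,fruit_shape_index,moisture_pct,hardness_N,flesh_thickness_mm,soluble_solids_pct,soluble_sugar_mg_g,soluble_sugar_pct,vitamin_c_mg_kg
CK,2.51 ± 0.08b,1.45 ± 0.03a,89.14 ± 0.40a,2.63 ± 0.32abc,37.49 ± 0.59abc,14.13 ± 0.64ab,1.02 ± 0.03 cd,13.43 ± 0.14c,3.15 ± 0.86bc
T1,2.37 ± 0.12bc,1.41 ± 0.12ab,88.78 ± 0.25a,2.17 ± 0.12d,34.39 ± 2.21c,13.50 ± 1.57ab,0.97 ± 0.05d,12.58 ± 0.92d,2.54 ± 0.12 cd
T2,1.99 ± 0.17d,1.39 ± 0.02abc,87.65 ± 1.25ab,2.43 ± 0.12bcd,39.25 ± 1.86abc,13.10 ± 0.66ab,0.95 ± 0.06d,12.48 ± 0.33d,2.41 ± 0.07d
T3,2.79 ± 0.13a,1.45 ± 0.05a,89.39 ± 1.74a,2.50 ± 0.10abcd,37.35 ± 3.94abc,12.73 ± 0.06b,0.98 ± 0.04d,12.97 ± 0.22 cd,2.71 ± 0.20 cd
T4,2.51 ± 0.13b,1.34 ± 0.11abc,87.87 ± 2.77ab,2.80 ± 0.26ab,40.28 ± 1.04ab,14.03 ± 1.30ab,1.04 ± 0.05 cd,13.52 ± 0.66c,3.65 ± 0.33b
T5,2.13 ± 0.23 cd,1.35 ± 0.03abc,84.50 ± 5.19b,2.37 ± 0.32 cd,34.67 ± 2.27bc,12.87 ± 0.85b,1.03 ± 0.11 cd,13.47 ± 0.16c,3.54 ± 0.14b
T6,2.39 ± 0.22bc,1.34 ± 0.05abc,87.98 ± 1.06ab,2.50 ± 0.17abcd,41.46 ± 1.59a,13.27 ± 0.81ab,1.14 ± 0.12bc,13.65 ± 0.44bc,3.69 ± 0.31b
T7,2.32 ± 0.16bc,1.27 ± 0.06c,88.53 ± 0.82ab,2.73 ± 0.31abc,37.26 ± 3.55abc,14.73 ± 1.10a,1.25 ± 0.03ab,14.39 ± 0.36ab,4.45 ± 0.35a
T8,2.21 ± 0.09 cd,1.30 ± 0.09bc,88.37 ± 1.33ab,2.87 ± 0.15a,40.17 ± 5.66ab,14.30 ± 0.62ab,1.21 ± 0.04ab,14.36 ± 0.27ab,4.43 ± 0.24a
T9,2.29 ± 0.11bc,1.28 ± 0.05bc,89.11 ± 1.86a,2.60 ± 0.10abc,35.16 ± 3.23bc,14.83 ± 0.15a,1.32 ± 0.09a,14.61 ± 0.09a,4.49 ± 0.34a
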