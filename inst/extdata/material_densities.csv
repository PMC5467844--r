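# Nominal densities (g/cm^3) for the materials tabulated in
# attenuation_tables.csv.
material,density_g_cm3
air,0.001205
water,1.000
muscle,1.050
bone_cortical,1.920
gold,19.32
aluminium,2.699
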