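# Approximate ICRU-44-style mass attenuation coefficients (cm^2/g).
# Values transcribed to ~1-2% from standard reference tabulations at the
# usual grid energies; gold carries a K-edge pair at 80.7 keV. Intended for
# synthetic CT simulation, not dosimetry. Log-log interpolate between rows.
material,energy_kev,mass_atten_cm2_g
air,10,5.120
air,15,1.614
air,20,0.7779
air,30,0.3538
air,40,0.2485
air,50,0.2080
air,60,0.1875
air,80,0.1662
air,100,0.1541
air,150,0.1356
water,10,5.329
water,15,1.673
water,20,0.8096
water,30,0.3756
water,40,0.2683
water,50,0.2269
water,60,0.2059
water,80,0.1837
water,100,0.1707
water,150,0.1505
muscle,10,5.356
muscle,15,1.693
muscle,20,0.8205
muscle,30,0.3783
muscle,40,0.2685
muscle,50,0.2262
muscle,60,0.2048
muscle,80,0.1823
muscle,100,0.1693
muscle,150,0.1492
bone_cortical,10,28.51
bone_cortical,15,9.032
bone_cortical,20,4.001
bone_cortical,30,1.331
bone_cortical,40,0.6655
bone_cortical,50,0.4242
bone_cortical,60,0.3148
bone_cortical,80,0.2229
bone_cortical,100,0.1855
bone_cortical,150,0.1480
gold,10,112.6
gold,15,96.2
gold,20,74.4
gold,30,26.1
gold,40,12.4
gold,50,6.93
gold,60,4.33
gold,70,2.88
gold,80.6,2.08
gold,80.8,8.90
gold,100,5.16
gold,150,1.86
aluminium,10,26.23
aluminium,15,7.955
aluminium,20,3.441
aluminium,30,1.128
aluminium,40,0.5685
aluminium,50,0.3681
aluminium,60,0.2778
aluminium,80,0.2018
aluminium,100,0.1704
aluminium,150,0.1378
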