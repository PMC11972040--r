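"condition","d_boron","d_neutron","d_photon","d_boron_sigma","surviving_fraction","sf_sigma","duration_min","colonies","cells_seeded"
"reference_photon",0,0,1,0,0.778571428571429,0.0430550983810122,0,327,600
"reference_photon",0,0,2,0,0.636904761904762,0.0275357940624295,0,535,1200
"reference_photon",0,0,4,0,0.31047619047619,0.0121591860331464,0,652,3000
"reference_photon",0,0,6,0,0.137301587301587,0.00466839402217547,0,865,9000
"reference_photon",0,0,8,0,0.0497023809523809,0.00172002181866665,0,835,24000
"beam_only",0,0.72,0.08,0,0.515873015873016,0.0286154863132063,10,325,900
"beam_only",0,1.44,0.16,0,0.170634920634921,0.0116372049989009,10,215,1800
"beam_only",0,2.88,0.32,0,0.00404761904761905,0.000981691815623253,10,17,6000
"beam_only",0,5.4,0.6,0,2.38095238095238e-05,4.76190476190476e-05,10,0,30000
"bpa_bnct",0.922273287532884,0.72,0.08,0.0461136643766442,0.025952380952381,0.00248578726402632,10,109,6000
"bpa_bnct",1.90843773640605,1.44,0.16,0.0954218868203025,0.000761904761904762,0.00019047619047619,10,16,30000
"bpa_bnct",3.62403566562059,2.88,0.32,0.181201783281029,4.76190476190476e-06,9.52380952380952e-06,10,0,150000
"bpa_bnct",6.8644008585944,5.4,0.6,0.34322004292972,7.93650793650794e-07,1.58730158730159e-06,10,0,9e+05
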