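metabolite,delta_h_ppm,delta_c_ppm,amplitude,lw_h_ppm,lw_c_ppm,long_range,selected
Trigonelline,9.12,148.4,1,0.03,0.5,0,1
Trigonelline,8.83,146.9,0.9,0.03,0.5,0,0
Trigonelline,8.07,129.8,0.8,0.03,0.5,0,0
Trigonelline,8.07,145.5,0.7,0.03,0.5,0,0
Trigonelline,4.43,57.2,0.8,0.03,0.5,0,0
Hippuric acid,7.82,129.6,1,0.03,0.5,0,1
Hippuric acid,7.63,133.8,0.8,0.03,0.5,0,0
Hippuric acid,7.55,129.9,0.9,0.03,0.5,0,0
Hippuric acid,3.96,46.4,0.7,0.03,0.5,0,0
Indoxyl sulphate,7.69,119.9,1,0.03,0.5,0,1
Indoxyl sulphate,7.5,115.3,0.8,0.03,0.5,0,0
Indoxyl sulphate,7.35,133.6,0.7,0.03,0.5,0,0
Indoxyl sulphate,7.28,105.5,0.8,0.03,0.5,0,0
Indoxyl sulphate,7.19,123.2,0.9,0.03,0.5,0,0
Phenylacetylglutamine,7.41,131.5,1,0.03,0.5,0,1
Phenylacetylglutamine,7.36,124.1,0.9,0.03,0.5,0,0
Phenylacetylglutamine,4.19,56.9,0.7,0.03,0.5,0,0
Phenylacetylglutamine,3.67,45.1,0.9,0.03,0.5,0,0
Phenylacetylglutamine,2.44,33.9,0.6,0.03,0.5,0,0
Phenylacetylglutamine,2.26,37.5,0.6,0.03,0.5,0,0
Phenylacetylglutamine,2.02,31.9,0.5,0.03,0.5,0,0
Phenylacetylglutamine,1.89,28.4,0.5,0.03,0.5,0,0
Phenylacetylglutamine,2.27,30.4,0.1,0.03,0.5,1,0
trans-Aconitic acid,6.58,133.5,1,0.03,0.5,0,1
trans-Aconitic acid,3.47,35.9,0.8,0.03,0.5,0,0
Levoglucosan,5.45,104,1,0.03,0.5,0,1
Levoglucosan,4.6,73.6,0.8,0.03,0.5,0,0
Levoglucosan,4.37,78.8,0.7,0.03,0.5,0,0
Levoglucosan,4.09,68.9,0.8,0.03,0.5,0,0
Levoglucosan,3.97,75.6,0.9,0.03,0.5,0,0
Levoglucosan,3.77,63,0.8,0.03,0.5,0,0
Levoglucosan,3.51,71.8,0.6,0.03,0.5,0,0
Carnitine,4.56,66.8,1,0.03,0.5,0,1
Carnitine,3.38,71.6,0.7,0.03,0.5,0,0
Carnitine,3.19,58.2,0.9,0.03,0.5,0,0
Carnitine,2.38,41.1,0.6,0.03,0.5,0,0
Creatine,3.92,56.5,1,0.03,0.5,0,1
Creatine,3.04,39.6,0.9,0.03,0.5,0,0
Mannitol,3.8,72,1,0.03,0.5,0,1
Mannitol,3.93,66.1,0.8,0.03,0.5,0,0
Mannitol,3.72,75.9,0.9,0.03,0.5,0,0
Mannitol,3.56,62.5,0.7,0.03,0.5,0,0
Erythritol,3.69,78.6,1,0.03,0.5,0,1
Erythritol,3.55,74.5,0.8,0.03,0.5,0,0
Erythritol,3.85,82.3,0.7,0.03,0.5,0,0
Galactitol,3.66,68.4,1,0.03,0.5,0,1
Galactitol,3.48,64.5,0.8,0.03,0.5,0,0
Galactitol,4.01,71.9,0.7,0.03,0.5,0,0
Taurine,3.44,38,1,0.03,0.5,0,1
Taurine,3.27,50.4,0.9,0.03,0.5,0,0
4-Hydroxyphenylacetic acid,3.44,46.1,1,0.03,0.5,0,1
4-Hydroxyphenylacetic acid,7.16,131.6,0.9,0.03,0.5,0,0
4-Hydroxyphenylacetic acid,6.86,116.4,0.9,0.03,0.5,0,0
Betaine,3.26,55.8,1,0.03,0.5,0,1
Betaine,3.9,70,0.7,0.03,0.5,0,0
Ethanolamine,3.14,44.2,1,0.03,0.5,0,1
Ethanolamine,3.78,59.2,0.8,0.03,0.5,0,0
Isocitric acid,2.98,51.6,1,0.03,0.5,0,1
Isocitric acid,2.86,42.3,0.8,0.03,0.5,0,0
Isocitric acid,2.62,86.1,0.8,0.03,0.5,0,0
Isocitric acid,4.14,74.6,0.6,0.03,0.5,0,0
Citric acid,2.54,48.1,1,0.03,0.5,0,1
Citric acid,2.75,51.9,0.9,0.03,0.5,0,0
Glutamine,2.14,29,1,0.03,0.5,0,1
Glutamine,2.45,31.6,0.8,0.03,0.5,0,0
Glutamine,3.77,45.6,0.8,0.03,0.5,0,0
Spermine,1.81,25.4,1,0.03,0.5,0,1
Spermine,3.11,47.3,0.8,0.03,0.5,0,0
Spermine,3.08,37.2,0.8,0.03,0.5,0,0
Spermine,2.1,24.2,0.7,0.03,0.5,0,0
Spermine,1.66,21.6,0.7,0.03,0.5,0,0
Lysine,1.7,29,1,0.03,0.5,0,1
Lysine,3.74,54.5,0.8,0.03,0.5,0,0
Lysine,3.01,41.8,0.8,0.03,0.5,0,0
Lysine,1.9,32.7,0.7,0.03,0.5,0,0
Lysine,1.47,31.4,0.7,0.03,0.5,0,0
Lysine,1.37,22.5,0.6,0.03,0.5,0,0
Adipic acid,1.5,24.8,1,0.03,0.5,0,1
Adipic acid,2.24,39.7,0.9,0.03,0.5,0,0
3-Hydroxyisovaleric acid,1.26,30.6,1,0.03,0.5,0,1
3-Hydroxyisovaleric acid,2.36,49.8,0.8,0.03,0.5,0,0
3-Aminoisobutanoic acid,1.2,17.6,1,0.03,0.5,0,1
3-Aminoisobutanoic acid,2.61,42.9,0.9,0.03,0.5,0,0
3-Aminoisobutanoic acid,2.3,46.9,0.7,0.03,0.5,0,0
3-Aminoisobutanoic acid,1.07,14.1,0.8,0.03,0.5,0,0
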