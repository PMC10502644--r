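entity,meta_entity,stiffness_ratio,fluidity_tumor,fluidity_control,heterogeneity,front,printed_pattern,clinical
Brain - Necrosis,,<=1,Fluid,Red.,+ (red.),Diffuse,3,Malignant
Liver - FNH,Liver - FNH,>1,Trans.,Solid,+ (red.),Sharp,2,Benign
Liver - HCA,Liver - HCA,<=1,Solid,Solid,+ (red.),Sharp,1,Benign
Liver - HEM,Liver - HEM,>1,Fluid,Solid,+,Sharp,4 (2),Benign
Liver - CCA,Liver - CCA,>1,Fluid,Solid,+,Sharp,4,Malignant
Liver - HCC,Liver - HCC,>1,Fluid,Trans.,+,Sharp,4,Malignant
Brain - MEN,Brain - MEN,<=1,Fluid,Solid/trans.,+,Sharp,1 (2),Benign
Brain - GM,Brain - GB,<=1,Solid,Solid/trans.,+,Diffuse,3 (4),Malignant
Pancreas Ca,Pancreas Ca 1,>1,Fluid,Trans.,+,Sharp,4,Malignant
Prostate Ca,Prostate PCa 1,>1,Fluid,Trans./fluid,+,Red.,4,Malignant
Colorectal Ca,Colorectal Ca,>1,Fluid,Solid/trans.,+ (red.),Diffuse,4,Malignant
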