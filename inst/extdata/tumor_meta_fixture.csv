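entity,role,control_tag,zone,c_mean,c_sd,fluidity_mean,fluidity_sd,n,study,c_converted_from_gstar,same_patient
Liver - HEM,tumor,,,1.97,0.45,0.21,0.38,11,Shahryari 2019,FALSE,TRUE
Liver - HEM,control,DTT,,1.37,0.13,-0.24,0.04,11,Shahryari 2019,FALSE,TRUE
Liver - HCA,tumor,,,1.41,0.21,-0.16,0.15,15,Shahryari 2019,FALSE,TRUE
Liver - HCA,control,DTT,,1.38,0.12,-0.16,0.08,15,Shahryari 2019,FALSE,TRUE
Liver - FNH,tumor,,,2.08,0.96,-0.07,0.31,10,Shahryari 2019,FALSE,TRUE
Liver - FNH,control,DTT,,1.40,0.12,-0.16,0.05,10,Shahryari 2019,FALSE,TRUE
Liver - CCA,tumor,,,2.57,0.90,0.58,0.32,12,Shahryari 2019,FALSE,TRUE
Liver - CCA,control,DTT,,1.72,0.29,-0.16,0.13,12,Shahryari 2019,FALSE,TRUE
Liver - HCC,tumor,,,2.54,0.64,0.53,0.37,22,Shahryari 2019,FALSE,TRUE
Liver - HCC,control,DTT,,1.97,0.49,0.03,0.20,22,Shahryari 2019,FALSE,TRUE
Brain - MEN,tumor,,,1.40,0.32,0.27,0.17,9,Streitberger 2020,TRUE,TRUE
Brain - MEN,control,CLH,,1.39,0.05,-0.26,0.09,9,Streitberger 2020,TRUE,TRUE
Brain - GB,tumor,,,1.07,0.28,-0.54,0.13,9,Streitberger 2020,TRUE,TRUE
Brain - GB,control,CLH,,1.42,0.18,-0.17,0.05,9,Streitberger 2020,TRUE,TRUE
Pancreas Ca 1,tumor,,,2.35,0.39,0.53,0.17,40,Zhu 2020,FALSE,TRUE
Pancreas Ca 1,control,HV,,1.32,0.05,0.03,0.05,10,Zhu 2020,FALSE,FALSE
Pancreas Ca 2,tumor,,,2.08,0.38,0.63,0.09,72,Marticorena 2020,FALSE,TRUE
Pancreas Ca 2,control,HV,,1.28,0.14,-0.01,0.09,30,Marticorena 2020,FALSE,FALSE
Prostate PCa 1,tumor,,,3.4,0.6,0.66,0.25,73,Li Guo 2021,FALSE,TRUE
Prostate PCa 1,control,HV,PZ,2.1,0.24,0.02,0.13,53,Li Guo 2021,FALSE,FALSE
Prostate PCa 1,control,HV,TZ,2.2,0.1,0.14,0.13,53,Li Guo 2021,FALSE,FALSE
Prostate PCa 2,tumor,,,3.1,0.6,0.40,0.13,14,Asbach 2020,FALSE,TRUE
Prostate PCa 2,control,BPH,PZ,2.8,0.4,0.15,0.25,25,Asbach 2020,FALSE,FALSE
Prostate PCa 2,control,BPH,TZ,2.8,0.3,0.15,0.13,25,Asbach 2020,FALSE,FALSE
Colorectal Ca,tumor,,,2.3,0.5,0.71,0.36,80,Hu Guo 2021,FALSE,TRUE
Colorectal Ca,control,DTT,,1.3,0.1,-0.087,0.10,80,Hu Guo 2021,FALSE,TRUE
Colorectal Ca,control,HV,,1.4,0.1,-0.06,0.13,12,Hu Guo 2021,FALSE,FALSE
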