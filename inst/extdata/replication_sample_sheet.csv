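"sample_id","subject_id","tissue","classification","gender","age_years","onset_age_years","duration_years","laterality","localisation","engel","mri_positive","risk_factors","prior_surgery","spike_enrichment_ratio"
"R001_brain","R001","brain","IIa",,,,,,,,,,,
"R001_blood","R001","blood","IIa",,,,,,,,,,,
"R002_brain","R002","brain","IIa",,,,,,,,,,,
"R002_blood","R002","blood","IIa",,,,,,,,,,,
"R003_brain","R003","brain","IIa",,,,,,,,,,,
"R003_blood","R003","blood","IIa",,,,,,,,,,,
"R004_brain","R004","brain","IIa",,,,,,,,,,,
"R004_blood","R004","blood","IIa",,,,,,,,,,,
"R005_brain","R005","brain","IIa",,,,,,,,,,,
"R005_blood","R005","blood","IIa",,,,,,,,,,,
"R006_brain","R006","brain","IIa",,,,,,,,,,,
"R006_blood","R006","blood","IIa",,,,,,,,,,,
"R007_brain","R007","brain","IIa",,,,,,,,,,,
"R007_blood","R007","blood","IIa",,,,,,,,,,,
"R008_brain","R008","brain","IIa",,,,,,,,,,,
"R008_blood","R008","blood","IIa",,,,,,,,,,,
"R009_brain","R009","brain","IIa",,,,,,,,,,,
"R009_blood","R009","blood","IIa",,,,,,,,,,,
"R010_brain","R010","brain","IIa",,,,,,,,,,,
"R010_blood","R010","blood","IIa",,,,,,,,,,,
"R011_brain","R011","brain","IIa",,,,,,,,,,,
"R011_blood","R011","blood","IIa",,,,,,,,,,,
"R012_brain","R012","brain","IIa",,,,,,,,,,,
"R012_blood","R012","blood","IIa",,,,,,,,,,,
"R013_brain","R013","brain","IIa",,,,,,,,,,,
"R013_blood","R013","blood","IIa",,,,,,,,,,,
"R014_brain","R014","brain","IIa",,,,,,,,,,,
"R014_blood","R014","blood","IIa",,,,,,,,,,,
"R015_brain","R015","brain","IIa",,,,,,,,,,,
"R015_blood","R015","blood","IIa",,,,,,,,,,,
"R016_brain","R016","brain","IIb",,,,,,,,,,,
"R016_blood","R016","blood","IIb",,,,,,,,,,,
"R017_brain","R017","brain","IIb",,,,,,,,,,,
"R017_blood","R017","blood","IIb",,,,,,,,,,,
"R018_brain","R018","brain","IIb",,,,,,,,,,,
"R018_blood","R018","blood","IIb",,,,,,,,,,,
"R019_brain","R019","brain","IIb",,,,,,,,,,,
"R019_blood","R019","blood","IIb",,,,,,,,,,,
"R020_brain","R020","brain","IIb",,,,,,,,,,,
"R020_blood","R020","blood","IIb",,,,,,,,,,,
"R021_brain","R021","brain","IIb",,,,,,,,,,,
"R021_blood","R021","blood","IIb",,,,,,,,,,,
"R022_brain","R022","brain","IIb",,,,,,,,,,,
"R022_blood","R022","blood","IIb",,,,,,,,,,,
"R023_brain","R023","brain","IIb",,,,,,,,,,,
"R023_blood","R023","blood","IIb",,,,,,,,,,,
"R024_brain","R024","brain","IIb",,,,,,,,,,,
"R024_blood","R024","blood","IIb",,,,,,,,,,,
"R025_brain","R025","brain","IIb",,,,,,,,,,,
"R025_blood","R025","blood","IIb",,,,,,,,,,,
"R026_brain","R026","brain","IIb",,,,,,,,,,,
"R026_blood","R026","blood","IIb",,,,,,,,,,,
"R027_brain","R027","brain","IIb",,,,,,,,,,,
"R027_blood","R027","blood","IIb",,,,,,,,,,,
"R028_brain","R028","brain","nonMCD",,,,,,,,,,,
"R028_blood","R028","blood","nonMCD",,,,,,,,,,,
"R029_brain","R029","brain","nonMCD",,,,,,,,,,,
"R029_blood","R029","blood","nonMCD",,,,,,,,,,,
"R030_brain","R030","brain","nonMCD",,,,,,,,,,,
"R030_blood","R030","blood","nonMCD",,,,,,,,,,,
"R031_brain","R031","brain","nonMCD",,,,,,,,,,,
"R031_blood","R031","blood","nonMCD",,,,,,,,,,,
"R032_brain","R032","brain","nonMCD",,,,,,,,,,,
"R032_blood","R032","blood","nonMCD",,,,,,,,,,,
"R033_brain","R033","brain","IIa",,,,,,,,,,,
"R034_brain","R034","brain","IIa",,,,,,,,,,,
"R035_brain","R035","brain","IIa",,,,,,,,,,,
"R036_brain","R036","brain","IIa",,,,,,,,,,,
"R037_brain","R037","brain","IIa",,,,,,,,,,,
"R038_brain","R038","brain","IIa",,,,,,,,,,,
"R039_brain","R039","brain","IIa",,,,,,,,,,,
"R040_brain","R040","brain","IIa",,,,,,,,,,,
"R041_brain","R041","brain","IIa",,,,,,,,,,,
"R042_brain","R042","brain","IIa",,,,,,,,,,,
"R043_brain","R043","brain","IIa",,,,,,,,,,,
"R044_brain","R044","brain","IIb",,,,,,,,,,,
"R045_brain","R045","brain","IIb",,,,,,,,,,,
"R046_brain","R046","brain","IIb",,,,,,,,,,,
"R047_brain","R047","brain","IIb",,,,,,,,,,,
"R048_brain","R048","brain","IIb",,,,,,,,,,,
"R049_brain","R049","brain","IIb",,,,,,,,,,,
"R050_brain","R050","brain","IIb",,,,,,,,,,,
"R051_brain","R051","brain","IIb",,,,,,,,,,,
"R052_brain","R052","brain","IIb",,,,,,,,,,,
"R053_brain","R053","brain","IIb",,,,,,,,,,,
"R054_brain","R054","brain","IIb",,,,,,,,,,,
"R055_brain","R055","brain","nonMCD",,,,,,,,,,,
"R056_brain","R056","brain","nonMCD",,,,,,,,,,,
"R057_brain","R057","brain","nonMCD",,,,,,,,,,,
"R058_brain","R058","brain","nonMCD",,,,,,,,,,,
"R059_brain","R059","brain","nonMCD",,,,,,,,,,,
"R060_brain","R060","brain","nonMCD",,,,,,,,,,,
"R061_brain","R061","brain","nonMCD",,,,,,,,,,,
"R062_blood","R062","blood","IIa",,,,,,,,,,,
"R063_blood","R063","blood","IIa",,,,,,,,,,,
"R064_blood","R064","blood","IIa",,,,,,,,,,,
"R065_blood","R065","blood","IIa",,,,,,,,,,,
"R066_blood","R066","blood","IIa",,,,,,,,,,,
"R067_blood","R067","blood","IIa",,,,,,,,,,,
"R068_blood","R068","blood","IIa",,,,,,,,,,,
"R069_blood","R069","blood","IIa",,,,,,,,,,,
"R070_blood","R070","blood","IIa",,,,,,,,,,,
"R071_blood","R071","blood","IIa",,,,,,,,,,,
"R072_blood","R072","blood","IIb",,,,,,,,,,,
"R073_blood","R073","blood","IIb",,,,,,,,,,,
"R074_blood","R074","blood","IIb",,,,,,,,,,,
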