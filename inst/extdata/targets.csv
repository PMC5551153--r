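target_name,aliases,kind,application_class,f_target,warnings
California red scale,aonidiella aurantii;crs,pest,internal,1.0,
Oleander scale,aspidiotus nerii,pest,internal,1.0,
Two-spotted spider mite,tetranychus urticae;tsm,pest,internal,1.0,
Citrus red mite,panonychus citri;red mite,pest,internal,1.0,
Citrus mealybug,planococcus citri,pest,internal,1.0,
Citrophilus mealybug,pseudococcus citri,pest,internal,1.0,
Black scale,saissetia oleae,pest,internal,1.0,
Chinese wax scale,ceroplastes sinensis,pest,internal,1.0,
Brown soft scale,coccus hesperidum,pest,internal,1.0,
Cottony cushion scale,icerya purchasi,pest,internal,1.0,no_authorized_products
Citrus brown spot (autumn),alternaria alternata autumn,disease,internal,1.0,
Thrips,pezothrips kellyanus,pest,intermediate,0.75,
Cotton aphid,aphis gossypii,pest,intermediate,0.75,
Green citrus aphid,aphis spiraecola,pest,intermediate,0.75,
Woolly whitefly,aleurothrixus floccosus,pest,intermediate,0.75,
Citrus leafminer,phyllocnistis citrella,pest,intermediate,0.75,
Carob moth,ectomyelois ceratoniae,pest,intermediate,0.75,
Honeydew moth,cryptoblabes gnidiella,pest,intermediate,0.75,
Citrus brown spot (spring),alternaria alternata spring,disease,intermediate,0.75,
Brown rot of citrus fruit,phytophthora brown rot,disease,intermediate,0.75,
Foot rot and gummosis,phytophthora foot rot;gummosis,disease,intermediate,0.75,trunk_application
Mediterranean fruit fly,ceratitis capitata;medfly,pest,external,0.49,bait_treatment
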