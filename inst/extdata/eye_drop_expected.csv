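"product_id","inn_name","relevant_links","availability_point","availability_category","price_band","affordability_point","affordability_category","probability","probability_category","total","total_provenance"
"betaxolol","Betaxolol",15,0.75,1,">50",0,0.25,0.25,"low",7,"reconstructed"
"brinzolamide","Brinzolamide",15,0.75,1,"25-50",0.5,0.5,0.5,"medium",6,"reconstructed"
"ciprofloxacin","Ciprofloxacin",4,0.2,0.25,"<25",1,1,0.25,"low",6,"reconstructed"
"sodium_cromoglicate","Sodium cromoglicate",11,0.55,0.5,"<25",1,1,0.5,"medium",5,"reconstructed"
"cyclopentolate","Cyclopentolate",4,0.2,0.25,">50",0,0.25,0.0625,"low",9,"printed"
"antazoline_tetryzoline","Tetryzoline & antazoline",4,0.2,0.25,"25-50",0.5,0.5,0.125,"low",5,"reconstructed"
"tetryzoline","Tetryzoline",4,0.2,0.25,"25-50",0.5,0.5,0.125,"low",5,"reconstructed"
"dorzolamide_timolol","Dorzolamide & timolol",20,1,1,"<25",1,1,1,"high",10,"printed"
"latanoprost_timolol","Latanoprost & timolol",3,0.15,0.25,"<25",1,1,0.25,"low",7,"reconstructed"
"travoprost","Travoprost",7,0.35,0.5,"25-50",0.5,0.5,0.25,"low",5,"reconstructed"
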