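"product_id","brand_name","inn_name","atc_code","dosage_form_class","application_instruction_count","mode_of_action_systemic","systemic_adr_documented","indication_damaged_or_inflamed","narrow_therapeutic_index","pediatric_indication_under6","multi_dose","antimicrobial_filter","contains_preservative","api_is_antibiotic","in_shortage","misuse_potential","registration_status","rx_only","local_adrs"
"betaxolol","BETOPTIC 5 mg/ml","Betaxolol","S01ED02","parenteral_or_topical",7,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",TRUE,"ocular discomfort|common|minor"
"brinzolamide","AZOPT 10 mg/ml","Brinzolamide","S01EC04","parenteral_or_topical",7,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",TRUE,"eye irritation|uncommon|minor"
"ciprofloxacin","CILOXAN 3 mg/ml","Ciprofloxacin","S03AA07","parenteral_or_topical",8,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,"registered",TRUE,"corneal precipitates|common|minor"
"sodium_cromoglicate","ALLEOPTI 20 mg/ml","Sodium cromoglicate","S01GX01","parenteral_or_topical",4,FALSE,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",FALSE,""
"cyclopentolate","HUMAPENT 5 mg/ml","Cyclopentolate","S01FA04","parenteral_or_topical",6,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,"registered",TRUE,""
"antazoline_tetryzoline","SPERSALLERG 0.5 mg/ml + 0.4 mg/ml","Tetryzoline & antazoline","S01GA52","parenteral_or_topical",6,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",FALSE,""
"tetryzoline","VISINE CLASSIC 0.5 mg/ml","Tetryzoline","S01GA02","parenteral_or_topical",5,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",FALSE,""
"dorzolamide_timolol","COSOPT UNO 20 mg/ml + 5 mg/ml","Dorzolamide & timolol","S01ED51","parenteral_or_topical",12,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,"registered",TRUE,"ocular burning|very_common|minor"
"latanoprost_timolol","XALACOM 0.05 mg/ml + 5 mg/ml","Latanoprost & timolol","S01ED51","parenteral_or_topical",9,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",TRUE,""
"travoprost","TRAVATAN 40 ug/ml","Travoprost","S01EE04","parenteral_or_topical",7,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,"registered",TRUE,""
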