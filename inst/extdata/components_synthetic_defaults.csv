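id,category,name,unit_label,selector_base,selector_fraction,dosage_frequency,group_size,usage_rate
social_marketing,promotion,Social marketing campaign,Campaign,total_population,1,1,25000,1
media_advocacy,promotion,Media advocacy events,Event,total_population,1,4,10000,1
community_coalitions,promotion,Community coalitions,Coalition,total_population,1,1,50000,1
school_programs,prevention,School-based programs,Single program event,age_10_19,1,2,150,0.8
community_programs,prevention,Community-based programs,Single program event,total_population,1,1,500,0.5
faith_programs,prevention,Faith-based programs,Short-term program,total_population,0.4,1,1000,0.3
workplace_programs,prevention,Workplace programs,Short-term program,age_20_65,0.6,1,5000,0.25
housing_vouchers,prevention,Housing vouchers,Voucher,substance_users,1,1,25,0.2
needle_exchanges,prevention,Needle exchanges,Needle exchange location,substance_users,0.1,12,1500,0.3
rx_disposal,prevention,Prescription drug disposal locations,Drop off location,total_population,1,1,5000,1
adult_drug_courts,referral,Adult drug courts,Drug court,substance_users,1,1,400,0.5
youth_drug_courts,referral,Youth drug courts,Drug court,age_10_19,1,1,2000,0.4
social_workers,referral,Social workers,Social worker,substance_users,1,4,3000,0.5
crisis_police,referral,Crisis-intervention-trained police,Police officer,total_population,1,1,10000,0.05
employee_assistance,referral,Employee assistance programs,Program,age_20_65,0.6,1,5000,0.2
primary_care_sa,referral,Primary care medical providers with specialty training in substance abuse,Health care professional,substance_users,1,2,250,0.5
inpatient_detox,treatment,Inpatient detoxification,Admissions,substance_users,1,1,1,0.04
inpatient_24h,treatment,Inpatient 24-h/intensive day treatment,Program,substance_users,1,1,20,0.15
inpatient_short,treatment,Inpatient short-term (30 days or fewer),Program,substance_users,1,1,40,0.1
inpatient_long,treatment,Inpatient long-term (more than 30 days),Program,substance_users,1,1,30,0.08
outpatient_detox,treatment,Outpatient detoxification,Admissions,substance_users,1,1,1,0.04
counselors,treatment,"Counselors, psychiatrists, or psychotherapists",Health care professional,substance_users,1,12,600,0.3
opiate_substitution,treatment,Office-based opiate substitution,Program,substance_users,0.2,1,100,0.3
religious_advisors,recovery,Religious or spiritual advisors,Religious community professional,substance_users,1,2,500,0.2
twelve_step,recovery,12-step groups,Meeting,substance_users,1,52,900,0.6
peer_support,recovery,Peer support groups,Group,substance_users,1,52,1200,0.4
transportation,recovery,Transportation,Round trip ride,substance_users,1,24,400,0.5
employment_support,recovery,Employment support,Social service professional,substance_users,1,2,800,0.3
educational_support,recovery,Educational support,Class,substance_users,1,4,150,0.4
parenting_education,recovery,Parenting education,Class,substance_users,0.5,2,100,0.3
housing_assistance,recovery,Housing assistance,Social service professional,substance_users,1,1,1000,0.3
insurance_assistance,recovery,Insurance assistance,Certified application counselor,substance_users,1,1,900,0.5
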