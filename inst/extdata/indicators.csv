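id,group,kind,threshold,units,description,source_note
voter_turnout,social,rate_below,35,% of eligible voters,Voter turnout below 35%,published threshold
hs_dropout,social,rate_above,12,% of students,High school dropout rate above 12%,published threshold
homeless,social,rate_above,2,% of population,Homeless population above 2%,published threshold
incarceration,social,rate_above,1.5,per 100 people,Incarceration rate above 1.5 per 100 people,published threshold
veterans,social,count_above,2000,persons,Veteran population above 2000 in the county,published threshold
foster_care,social,rate_above,5,per 100 people,Previously-in-foster-care rate above 5 per 100 people,published threshold
low_income_households,social,rate_above,12,% of households,More than 12% of households with income under $35000,published threshold
median_income,social,rate_above,53000,USD,Median household income above $53000,published threshold; exceedance flags as printed
college_degree,social,rate_above,30,% of adults,More than 30% hold a college degree,published threshold; exceedance flags as printed
divorced_widowed_separated,social,rate_above,3.5,per 1000 people per year,"Divorced, widowed, or separated rate above 3.5 per 1000 in the past year",published threshold
uninsured,social,rate_above,20,% of population,Percentage uninsured above 20%,published threshold
hidta,community,boolean,,designation,County designated as a high-incidence drug trafficking area,published indicator
alcohol_outlets,community,rate_above,0.4,liquor stores per 10000 people,Alcohol outlet density above 0.4 liquor stores per 10000 people,published threshold
employer_collapse,community,boolean,,event,Collapse of a major employer,published indicator
university,community,boolean,,presence,Presence of a university,published indicator
military_base,community,boolean,,presence,Presence of a military base,published indicator
violent_crime,community,rate_above,300,per 100000 people,Violent crime rate above 300 per 100000 people,published threshold
exercise_access,community,rate_above,50,% of population,Access to exercise opportunities above 50%,published threshold; exceedance flags as printed
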