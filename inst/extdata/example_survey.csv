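"respondent_id","best","worst","gender","age_group","race","education","relationship","employment"
"E001","spiritual","social","Female","Seniors (65+)","White","Bachelor's degree","Married and living with spouse","Retired"
"E002","economic","community","Male","Adults (25-54)","Black or African American","Bachelor's degree","Single","Working full-time"
"E003","health","social","Female","Adults (25-54)","White","Some college but did not complete degree","Single","Working full-time"
"E004","spiritual","community","Female","Early Seniors (55-64)","Black or African American","Master's degree or higher","Married and living with spouse","Retired"
"E005","food","social","Male","Adults (25-54)","White","Some high school","Single","Unemployed"
"E006","economic","social","Male","Adults (25-54)","White","Bachelor's degree","Single","Working full-time"
"E007","health","community","Female","Adults (25-54)","Black or African American","High school graduate or GED completed","Single","Working full-time"
"E008","spiritual","social","Female","Seniors (65+)","White","Master's degree or higher","Married and living with spouse","Retired"
"E009","spiritual","social","Female","Early Seniors (55-64)","","Bachelor's degree","Married and living with spouse","Retired"
"E010","health","","Male","Adults (25-54)","White","Associate's degree","Single","Working part-time"
"E011","economic","economic","Male","Adults (25-54)","White","Bachelor's degree","Single","Working full-time"
"E012","food","social","Female","Adults (25-54)","Black or African American","Some high school","Single","Unemployed"
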