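subject_id,diagnosis,donor_type,conditioning,gvhd_prophylaxis,consolidation_regimen,consolidation_start_day,relapse_day,death_day,death_cause,last_followup_day,adverse_at_diagnosis
001,AML,URD 10/10,MA + ATG,MTX,NA,NA,NA,59,regimen-related toxicity,59,TRUE
002,t-MDS,URD 10/10,MA + ATG,MTX + Abat,NA,NA,170,NA,NA,365,TRUE
003,MDS,URD 8/10,NMA,PTCy + Abat,NA,NA,NA,NA,NA,365,TRUE
004,AML,URD 10/10,MA + ATG,MTX + Abat,Sorafenib + HMA,51,NA,357,infection,357,FALSE
005,t-MDS,URD 10/10,RIC + ATG,MTX + Abat,HMA + DLI,121,NA,NA,NA,365,TRUE
006,2nd-AML (CMML),URD 10/10,RIC + ATG,MTX + Abat,NA,NA,NA,NA,NA,365,TRUE
007,2nd-AML (MDS),URD 10/10,NMA,PTCy + Abat,NA,NA,62,250,relapse,250,TRUE
008,AML,Haplo,RIC,PTCy,Crenolinib + sorafenib,91,NA,NA,NA,365,TRUE
009,AML,RD 10/10,RIC + ATG,MTX,HMA + MT401 DLI,76,168,285,relapse,285,TRUE
010,2nd-AML,Haplo,NMA,PTCy + Abat,NA,NA,52,125,relapse,125,TRUE
011,2nd-AML (MDS),URD 9/10,RIC,PTCy + Abat,HMA,88,NA,NA,NA,365,TRUE
012,MDS,URD 10/10,MA + ATG,MTX + Abat,NA,NA,167,NA,NA,365,TRUE
013,MDS,URD 10/10,RIC + ATG,MTX + Abat,NA,NA,139,NA,NA,365,TRUE
015,AML,RD 10/10,MA,MTX,Midostaurin + gilteritinib,35,NA,NA,NA,365,TRUE
016,MDS,URD 10/10,RIC + ATG,MTX + Abat,HMA,89,NA,268,sepsis,268,TRUE
017,CML,URD 10/10,RIC,MTX + Abat,Imatinib,52,NA,NA,NA,365,TRUE
018,2nd-AML (BrCa),URD 10/10,RIC,MTX + Abat,NA,NA,NA,NA,NA,365,TRUE
019,2nd-AML (MF),Haplo,NMA,PTCy,NA,NA,NA,NA,NA,365,TRUE
020,AML,URD 10/10,MA + ATG,MTX + Abat,NA,NA,NA,NA,NA,365,TRUE
021,MDS,URD 10/10,RIC + ATG,MTX + Abat,Sorafenib,77,NA,NA,NA,365,TRUE
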