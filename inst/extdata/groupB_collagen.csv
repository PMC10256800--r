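subject,contour,grade_label,artifact_suspect
A,HHV,no significant,FALSE
B,HHV,no significant,FALSE
C,HHV,no significant,FALSE
D,HHV,minimal,TRUE
E,HHV,minimal,TRUE
A,HLV,marked,FALSE
B,HLV,moderate,FALSE
C,HLV,moderate,FALSE
D,HLV,moderate,FALSE
E,HLV,mild-moderate,FALSE
A,LLV,minimal-mild,FALSE
B,LLV,minimal,FALSE
C,LLV,minimal,FALSE
D,LLV,minimal,FALSE
E,LLV,no significant,FALSE
A,MD,moderate-marked,FALSE
B,MD,moderate,FALSE
C,MD,moderate-marked,FALSE
D,MD,mild-moderate,FALSE
E,MD,moderate,FALSE
A,LDF,no significant,FALSE
B,LDF,moderate-marked,FALSE
C,LDF,moderate,FALSE
D,LDF,mild,FALSE
E,LDF,minimal,FALSE
A,LDNF,no significant,FALSE
B,LDNF,no significant,FALSE
C,LDNF,no significant,FALSE
D,LDNF,no significant,FALSE
E,LDNF,no significant,FALSE
A,NDF,no significant,FALSE
B,NDF,no significant,FALSE
C,NDF,mild-moderate,FALSE
D,NDF,no significant,FALSE
E,NDF,no significant,FALSE
A,NDNF,mild,FALSE
B,NDNF,no significant,FALSE
C,NDNF,no significant,FALSE
D,NDNF,minimal,FALSE
E,NDNF,no significant,FALSE
A,CON,no significant,FALSE
B,CON,no significant,FALSE
C,CON,no significant,FALSE
D,CON,no significant,FALSE
E,CON,no significant,FALSE
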