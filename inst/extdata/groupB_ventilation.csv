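subject,contour,change_class,ratio
A,HHV,Stable,NA
B,HHV,Stable,NA
C,HHV,Stable,NA
D,HHV,Stable,NA
E,HHV,Stable,NA
A,HLV,Decline,0.84
B,HLV,Decline,NA
C,HLV,Decline,NA
D,HLV,Decline,NA
E,HLV,Decline,NA
A,LLV,Stable,NA
B,LLV,Stable,NA
C,LLV,Stable,NA
D,LLV,Stable,NA
E,LLV,Stable,NA
A,MD,Decline,NA
B,MD,Decline,NA
C,MD,Decline,NA
D,MD,Decline,NA
E,MD,Decline,NA
A,LDF,Stable,NA
B,LDF,Stable,NA
C,LDF,Decline,NA
D,LDF,Decline,NA
E,LDF,Decline,NA
A,LDNF,Stable,NA
B,LDNF,Stable,NA
C,LDNF,Stable,NA
D,LDNF,Stable,NA
E,LDNF,Stable,NA
A,NDF,Stable,NA
B,NDF,Stable,NA
C,NDF,Decline,NA
D,NDF,Decline,NA
E,NDF,Decline,NA
A,NDNF,Stable,NA
B,NDNF,Stable,NA
C,NDNF,Stable,NA
D,NDNF,Stable,NA
E,NDNF,Stable,NA
A,CON,Stable,NA
B,CON,Stable,NA
C,CON,Stable,NA
D,CON,Stable,NA
E,CON,Stable,NA
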