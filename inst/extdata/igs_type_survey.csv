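igs_type,isolate_count,representatives,clade,species
20,9,CDYB-22,C1,Rhizobium sophorae
18,9,CNHH-10,C2,Rhizobium acidisoli
13,11,DEYH-16,C3,Rhizobium ecuadorense
10,16,DMDH-21,C4,Rhizobium genosp. I
30,5,BSDB-6,C4,Rhizobium genosp. I
43,1,BSDH-6,C5,Rhizobium hidalgonense
25,6,DWSB-10,C5,Rhizobium hidalgonense
42,1,DXYH-4,C5,Rhizobium hidalgonense
37,3,DWSH-6,C5,Rhizobium hidalgonense
41,1,CMDH-27,C5,Rhizobium hidalgonense
8,16,CMDH-4,C5,Rhizobium hidalgonense
32,4,CLFH-5,C5,Rhizobium hidalgonense
39,2,CDHH-14,C6,Rhizobium vallis
12,12,CDHH-1,C6,Rhizobium vallis
28,5,CWDB-3,C7,Rhizobium sophoriradicis
23,8,CDYH-7,C8,Rhizobium croatiense
3,44,BCNB-10;CYAH-6,C8,Rhizobium croatiense
15,10,CYAH-5,C8,Rhizobium croatiense
6,19,CYAH-25,C8,Rhizobium croatiense
21,9,CDYB-13,C8,Rhizobium croatiense
1,153,CDYH-5;CDYH-21,C9,Rhizobium anhuiense
29,5,DWSB-11,C9,Rhizobium anhuiense
11,13,CYAB-3,C9,Rhizobium anhuiense
34,4,CSBH-8,C9,Rhizobium anhuiense
14,10,CMDH-25,C10,Rhizobium genosp. II
2,63,CMDB-13,C11,Rhizobium phaseoli
40,2,CNHB-19,C11,Rhizobium phaseoli
4,38,CMDH-26;DXYB-3,C11,Rhizobium phaseoli
38,3,DXYH-20,C11,Rhizobium phaseoli
22,9,BSDH-15,C11,Rhizobium phaseoli
36,3,DXYB-25,C11,Rhizobium phaseoli
7,17,DXYB-19,C11,Rhizobium phaseoli
16,10,CSBH-19,C11,Rhizobium phaseoli
33,4,CSBH-3,C11,Rhizobium phaseoli
26,5,CMDH-5,C11,Rhizobium phaseoli
9,16,CLFH-22,C11,Rhizobium phaseoli
24,6,CDYB-4,C12,Rhizobium genosp. III
27,5,DWSB-18,C13,Rhizobium chutanense
35,3,CNHB-17,C13,Rhizobium chutanense
5,26,CDHB-7,C13,Rhizobium chutanense
31,4,CMDB-12,C14,Rhizobium etli
17,9,BLYB-15,C15,Rhizobium genosp. IV
19,9,BLYH-17,C16,Rhizobium genosp. V
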