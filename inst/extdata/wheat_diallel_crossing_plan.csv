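# Crossing plan of the bundled wheat partial diallel: 7 male lines x 11 female
# testers, 23 realized crosses. Hybrid labels use the trial MALE/FEMALE naming.
record,id,sex_role,pedigree,hybrid_id,female_id,male_id
parent,P1,male,,,,
parent,P3,male,,,,
parent,P4,male,,,,
parent,P9,male,,,,
parent,P10,male,,,,
parent,P13,male,,,,
parent,P16,male,,,,
parent,P2,female,,,,
parent,P5,female,,,,
parent,P6,female,,,,
parent,P7,female,,,,
parent,P8,female,,,,
parent,P11,female,,,,
parent,P12,female,,,,
parent,P14,female,,,,
parent,P15,female,,,,
parent,P17,female,,,,
parent,P18,female,,,,
cross,,,,P1/P2,P2,P1
cross,,,,P1/P6,P6,P1
cross,,,,P1/P8,P8,P1
cross,,,,P1/P18,P18,P1
cross,,,,P3/P2,P2,P3
cross,,,,P3/P6,P6,P3
cross,,,,P3/P8,P8,P3
cross,,,,P3/P18,P18,P3
cross,,,,P4/P7,P7,P4
cross,,,,P4/P11,P11,P4
cross,,,,P4/P17,P17,P4
cross,,,,P9/P2,P2,P9
cross,,,,P9/P6,P6,P9
cross,,,,P9/P8,P8,P9
cross,,,,P9/P18,P18,P9
cross,,,,P10/P5,P5,P10
cross,,,,P10/P12,P12,P10
cross,,,,P10/P14,P14,P10
cross,,,,P10/P15,P15,P10
cross,,,,P13/P7,P7,P13
cross,,,,P13/P11,P11,P13
cross,,,,P16/P7,P7,P16
cross,,,,P16/P11,P11,P16
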