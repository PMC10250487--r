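bin,formula,accurate_mass,lipid_id,lipid_class
127.1,C7H12O2,127.0759,FA 7:1,FA0103
239.1,C15H28O2,239.2011,FA 15:1,FA0103
277.3,C18H30O2,277.2168,FA 18:3,FA0103
301.3,C20H30O2,301.2168,FA 20:5,FA0103
327.3,C22H32O2,327.2324,FA 22:6,FA0103
337.3,C22H42O2,337.3107,FA 22:1,FA0103
255.3,C16H32O2,255.2324,FA 16:0,FA0102
279.3,C18H32O2,279.2330,FA 18:2,FA0102
281.3,C18H34O2,281.2481,FA 18:1,FA0102
309.3,C20H38O2,309.2794,FA 20:1,FA0102
280.3,C14H23N3O3,280.1667,Amide C14H23N3O3,Primary amide
282.3,C18H37NO,282.2797,Amide C18H37NO,Primary amide
128.1,C7H15NO,128.1075,NA 7:0,FA0802
222.1,C14H25NO,222.1863,NA 14:2,FA0802
338.3,C20H37NO3,338.2701,NA 20:2,FA0802
745.5,C40H75O10P,745.5020,PG 34:2,Diacylglycerophosphoglycerol
790.5,C45H78NO8P,790.5387,PC 37:6,Diacylglycerophosphocholine
909.5,C60H94O6,909.6972,TG 57:11,Triacylglycerol
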