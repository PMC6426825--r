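species,category,two_n,n_m,n_sm,n_st,n_t,fn,ls_ratio,mean_ar,stebbins_class,source
Urechis unicinctus,echiuran,30,10,6,6,8,52,2.51,2.54,3B,this_study
Achaetobonellia maculata,echiuran,20,20,0,0,0,40,3.96,1.03,1A,literature
Sipunculus nudus,sipunculid,34,26,8,0,0,68,1.68,1.56,2A,literature
Phascolosoma esculenta,sipunculid,20,4,10,6,0,40,1.66,2.48,3A,literature
Nereis oligohalina,polychaete,28,14,2,6,6,50,2.54,2.01,4B,literature
Perinereis anderssoni,polychaete,38,20,8,0,0,56,2.77,1.64,2B,literature
Hediste diversicolor,polychaete,28,16,4,8,0,56,2.61,2.12,2B,literature
Drawida ghilarovi,oligochaete,20,6,8,6,0,48,2.46,2.39,3B,literature
Eisenia balatonica,oligochaete,36,10,20,6,0,72,2.75,2.38,3B,literature
Aporrectodea caliginosa,oligochaete,36,12,18,6,0,72,2.38,2.05,2B,literature
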