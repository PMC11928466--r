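compartment,tau,rk4,rpsm,gwcm,flagged
S,0.00,620.000000000000000,620.000000000000000,620.00000000000000,FALSE
S,0.10,619.368327701129830,619.368327657510350,619.3683276172103,FALSE
S,0.20,618.702153816378770,618.702153724652930,618.7021536932915,FALSE
S,0.30,617.999682039910570,617.999681895280220,617.9996818627100,FALSE
S,0.40,617.259032603941480,617.259032401282640,617.2590323636210,FALSE
S,0.50,616.478239561945540,616.478239295794650,616.4782421581235,FALSE
S,0.60,615.655248125904110,615.655247790443130,615.6552477513076,FALSE
S,0.70,614.787912080138200,614.787911669181200,614.7879116245700,FALSE
S,0.80,613.873991297021010,613.873990803999960,613.8739907574077,FALSE
S,0.90,612.911149382834760,612.911148800787370,612.9111487634786,FALSE
S,1.00,611.896951485213090,611.896950806769950,611.8969507254561,FALSE
I,0.00,10.000000000000000,10.000000000000000,10.000000000000000,FALSE
I,0.10,10.557682415377140,10.557682454124135,10.557682492954838,FALSE
I,0.20,11.145742665297318,11.145742746766953,11.145742776768072,FALSE
I,0.30,11.765752718571312,11.765752847013921,11.765752878029145,FALSE
I,0.40,12.419356430322715,12.419356610275818,12.419356646042534,FALSE
I,0.50,13.108271733277171,13.108271969577906,13.108272005874188,FALSE
I,0.60,13.834292759467655,13.834293057265034,13.834293094072999,FALSE
I,0.70,14.599291870396474,14.599292235163372,14.599292277067361,FALSE
I,0.80,14.599291870396474,15.405222008647254,15.405222052236754,TRUE
I,0.90,16.254116280801693,16.254116797279011,16.254116831658386,FALSE
I,1.00,17.148093929799238,17.148094531720652,17.148094608528900,FALSE
R,0.00,70.000000000000000,70.000000000000000,70.000000000000000,FALSE
R,0.10,70.073989883493013,70.073989888365404,70.073989889834900,FALSE
R,0.20,70.152103518323841,70.152103528579929,70.152103529940400,FALSE
R,0.30,70.234565241518069,70.234565257705697,70.234565259260900,FALSE
R,0.40,70.321610965735758,70.321610988441307,70.321610990336480,FALSE
R,0.50,70.413488704777279,70.413488734627379,70.413488736739170,FALSE
R,0.60,70.510459114628276,70.510459152291887,70.510459154619450,FALSE
R,0.70,70.612796049465331,70.612796095655639,70.612796098362640,FALSE
R,0.80,70.720787131876406,70.720787187352826,70.720787190355570,FALSE
R,0.90,70.834734336363510,70.834734401933645,70.834734404863070,FALSE
R,1.00,70.954954584987661,70.954954661509220,70.954954666014880,FALSE
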