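"row_id","rt","deconvoluted_mass","predicted_mass","iso_mz","sequence","labels","identified","note"
1,8.81,856.3,855,"855.30","G*G*","5'N-16",TRUE,""
2,8.98,970.35,971,"969.92","mU*mC*MoeR;mC*mU*MoeR","3'N-16;5'N-6+3'N-10;5'N-3+3'N-13;5'N-14+3'N-2",TRUE,""
3,9.21,1128.42,1128,"1127.35","G*mU*mC;mU*G*mC","5'N-14+3'N-1;5'N-12+3'N-3",TRUE,""
4,9.44,1464.62,1464,"731.35;1463.73","*mU*mU*mU*MoeR","5'N-4+3'N-11",TRUE,""
5,9.46,1308.52,1308,"653.21;1307.43","*A*A*mU*;*mU*A*A*","5'N-10+3'N-5;5'N-9+3'N-6",TRUE,""
6,9.48,1106.47,1104,"1105.37","mU*mU*mU","5'N-4+3'N-11",TRUE,""
7,9.51,1193.49,1194,"593.48;1185.97","mC*mU*mU*;mU*mU*mC*","5'N-3+3'N-12;5'N-5+3'N-10",TRUE,""
8,9.54,1349.6,1349,"673.84;1348.70","MoeR*mU*A*MoeR*;MoeR*A*mU*MoeR*","5'N-11+3'N-5;5'N-8+3'N-8;5'N-9+3'N-7",TRUE,""
9,9.63,1205.55,1205,"602.07;1205.15","mC*A*mU*;mU*mC*A*;A*mC*mU*","5'N-7+3'N-8;3'N-15;5'N-2+3'N-13",TRUE,""
10,9.97,1615.62,1614,"806.85;1614.71","A*mU*A*A*","5'N-8+3'N-6",TRUE,""
11,10,1544.59,1543,"771.23;1543.48","G*G*mU*mC","3'N-14",TRUE,""
12,10.04,1459.52,1458,"728.72;1458.45","A*mC*mU*MoeR*;mU*mC*A*MoeR*;mC*A*mU*MoeR*","5'N-2+3'N-13;5'N-6+3'N-9;5'N-7+3'N-8",TRUE,""
13,10.28,1324.49,1325,"661.29;1323.58","*A*mU*G*","5'N-11+3'N-4",TRUE,"shares label 5'N-11+3'N-4 with the 1237.46 species at a different mass; probable erratum"
14,10.45,1237.46,1233,"617.59;1236.39","A*mU*G*","5'N-11+3'N-4",TRUE,"shares label 5'N-11+3'N-4 with the 1324.49 species; printed predicted mass 1233 is 4.5 Da below the deconvoluted value"
15,10.45,1499.47,1499,"748.73;1498.47","mU*mC*A*mC","3'N-14;5'N-1+3'N-13",TRUE,"printed deconvoluted mass inconsistent with the printed ions (ion pair implies 1499.59); probable erratum"
16,10.6,1395.41,1395,"696.70;1394.41","G*mU*mC*MoeR;mU*G*mC*MoeR","5'N-15+3'N-1;5'N-12+3'N-3",TRUE,"printed deconvoluted mass inconsistent with the printed ions (ion pair implies 1395.54); elsewhere the -1 ion is quoted as 1394.52"
17,10.83,1396.5,1396,"697.30;1395.41","","",FALSE,"unidentified species"
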