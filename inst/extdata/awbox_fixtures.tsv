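gene_name	strand	seq	tis_start	tis_end	in_utr5	tested_in_emsa	emsa_label	variant	insertion_offset	mutant_of	note
aPDH-13g	+	CCTCGTTCACTCCG	-101	-88	TRUE	TRUE	bound	canonical	NA	NA	-
bPDH-4g	-	CTTCGATTGTGCCG	-168	-155	TRUE	TRUE	unbound	canonical	NA	NA	tested-inferred
bPDH-16g	-	CTTTGGTTGTAACG	-179	-166	TRUE	TRUE	bound	canonical	NA	NA	-
bPDH-16g	-	CATTGCGTTTTACG	-958	-945	FALSE	FALSE	untested	canonical	NA	NA	end-recomputed
bPDH-17g	+	CATTGATTTCTCCG	-99	-86	TRUE	TRUE	bound	canonical	NA	NA	-
bPDH-17g	-	CATAGTAACACCCG	-276	-263	FALSE	TRUE	unbound	canonical	NA	NA	-
bPDH-17g	-	CGTGGGCGTCATCG	-464	-451	FALSE	TRUE	unbound	canonical	NA	NA	-
LPD-10g	-	CTTCGAGAGGTCCG	-73	-60	TRUE	TRUE	bound	canonical	NA	NA	-
LPD-10g	+	CATTGTTAACTCCG	-98	-85	TRUE	TRUE	bound	canonical	NA	NA	-
LPD-16g	+	CGTCGTCTCCCCCG	-112	-99	TRUE	TRUE	unbound	canonical	NA	NA	-
LPD-16g	+	CTTCGTTAACTCCG	-127	-114	TRUE	TRUE	bound	canonical	NA	NA	-
DHLAT-4g	-	CGTTGGTTAGCGCG	-641	-628	FALSE	FALSE	untested	canonical	NA	NA	tested-inferred
DHLAT-4g	-	CGTCGTATCTACCG	-675	-662	FALSE	FALSE	untested	canonical	NA	NA	tested-inferred;end-recomputed
DHLAT-8g	-	CTTAGGCCTTAACG	-703	-690	FALSE	FALSE	untested	canonical	NA	NA	tested-inferred
DHLAT-12g	+	CCTCGTCTTCTCCG	-105	-92	TRUE	TRUE	bound	canonical	NA	NA	-
aCT-10g	-	CATAGAGAAGATCG	-915	-902	TRUE	TRUE	bound	canonical	NA	NA	-
aCT-10g	+	CATAGAACTCATCG	-1095	-1082	FALSE	FALSE	untested	canonical	NA	NA	-
aCT-10g	-	CGTCGAAAATCCCG	-1383	-1370	FALSE	FALSE	untested	canonical	NA	NA	-
aCT-10g	-	CTTGGAATTTTTCG	-1406	-1393	FALSE	FALSE	untested	canonical	NA	NA	-
aCT-15g	-	CATAGAGAAGATCG	-870	-857	TRUE	TRUE	bound	canonical	NA	NA	-
aCT-15g	-	CATGGGTGGGTTCG	-995	-982	TRUE	TRUE	unbound	canonical	NA	NA	-
BC-16g	+	CATAGATTTCATCG	-334	-321	TRUE	TRUE	smear	canonical	NA	NA	-
BC-16g	+	CGTTGTCTAAATCG	-1042	-1029	FALSE	FALSE	untested	canonical	NA	NA	-
BC-16g	-	CGTCGAAAATCCCG	-1217	-1204	FALSE	FALSE	untested	canonical	NA	NA	-
BC-16g	-	CTTGGAATTTTTCG	-1240	-1227	FALSE	FALSE	untested	canonical	NA	NA	-
BC-16g	-	CCTTGAATTTTTCG	-1262	-1249	FALSE	FALSE	untested	canonical	NA	NA	-
BC-16g	-	CTTGGAATTTTTCG	-1285	-1272	FALSE	FALSE	untested	canonical	NA	NA	-
BCCP-2g	+	CTTTGTTGATATCG	-104	-91	TRUE	TRUE	smear	canonical	NA	NA	-
BCCP-9g	+	CCTCGGTCATATCG	-123	-110	TRUE	TRUE	bound	canonical	NA	NA	-
BCCP-9g	-	CTTTGTTACAGGCG	-1004	-991	FALSE	FALSE	untested	canonical	NA	NA	-
BCCP-16g	+	CTTCGGTTCCCTCG	-92	-79	TRUE	TRUE	unbound	canonical	NA	NA	-
BCCP-16g	+	CCTCGTTGATATCG	-136	-123	TRUE	TRUE	bound	canonical	NA	NA	-
BCCP-16g	-	CCTCGTGTGTCACG	-252	-239	TRUE	TRUE	bound	canonical	NA	NA	-
BCCP-16g	+	CATCGCATAAACCG	-1048	-1035	FALSE	TRUE	unbound	canonical	NA	NA	-
BCCP-16g	+	CTTCGAATAAATCG	-1203	-1190	FALSE	TRUE	unbound	canonical	NA	NA	-
BCCP-16g	-	CTTAGGCGACAGCG	-1242	-1229	FALSE	TRUE	unbound	canonical	NA	NA	-
LS-5g	-	CCTTGTCAAGTACG	-867	-854	FALSE	FALSE	untested	canonical	NA	NA	-
LS-12g	-	CATGGCTGTCTACG	-570	-557	FALSE	FALSE	untested	canonical	NA	NA	-
LT-5g	+	CTTCGGTCACTCCG	-42	-29	TRUE	FALSE	untested	canonical	NA	NA	end-recomputed;not-in-CAS6
ACP1-7g	+	CATTGTACCCTCCG	-40	-27	TRUE	TRUE	unbound	canonical	NA	NA	-
ACP1-7g	-	CATCGGGATATCCG	-126	-113	TRUE	TRUE	bound	canonical	NA	NA	-
ACP2-14g	+	CATCGTCTCCTCCG	-65	-52	TRUE	TRUE	unbound	canonical	NA	NA	-
ACP2-14g	-	CATCGAGAAATCCG	-124	-111	TRUE	TRUE	bound	canonical	NA	NA	end-recomputed
ACP2-14g	+	CGTCGTTGCCGACG	-859	-846	FALSE	FALSE	untested	canonical	NA	NA	both-strands-listed
ACP2-14g	-	CGTCGGCAACGACG	-859	-846	FALSE	FALSE	untested	canonical	NA	NA	both-strands-listed
ACP2-14g	-	CCTGGGTGATAACG	-882	-869	FALSE	FALSE	untested	canonical	NA	NA	-
ACP2-14g	-	CGTCGTTTCCATCG	-1195	-1182	FALSE	FALSE	untested	canonical	NA	NA	-
KASI-1g	+	CGTTGTTATTTACG	-991	-978	FALSE	FALSE	untested	canonical	NA	NA	-
KASI-17g	+	CATCGTTTATATCG	-101	-88	TRUE	TRUE	bound	canonical	NA	NA	end-recomputed
KASII-15g	+	CCTGGAAACAAACG	-1240	-1227	FALSE	FALSE	untested	canonical	NA	NA	end-recomputed
KASII-15g	+	CTTTGGGTTTTTCG	-1290	-1277	FALSE	FALSE	untested	canonical	NA	NA	-
KASIII-2g	-	CATTGAGAAGAACG	-71	-58	TRUE	TRUE	unbound	canonical	NA	NA	overlapping-boxes
KASIII-2g	-	CTTCGGAGTAGTCG	-109	-96	TRUE	TRUE	unbound	canonical	NA	NA	overlapping-boxes
KASIII-2g	+	CTTCGACTACTCCG	-112	-99	TRUE	TRUE	unbound	canonical	NA	NA	overlapping-boxes
KASIII-5g	+	CCTCGACTACTCCG	-209	-196	TRUE	TRUE	bound	canonical	NA	NA	-
KASIII-17g	+	CTTGGAGTACTCCG	-277	-264	FALSE	TRUE	unbound	canonical	NA	NA	-
KASIII-17g	+	CGTGGTGTCTACCG	-342	-329	FALSE	TRUE	unbound	canonical	NA	NA	-
KASIII-17g	+	CCTTGAGCCAAACG	-376	-363	FALSE	TRUE	unbound	canonical	NA	NA	-
KAR1-17g	+	CTTAGATTATATCG	-130	-117	TRUE	TRUE	smear	canonical	NA	NA	-
KAR1-17g	+	CTTAGGTTATATCG	NA	NA	NA	TRUE	unbound	canonical	NA	KAR1-17g:-130:mutA/G	synthetic-probe
KAR1-17g	+	CTTCGATTATATCG	NA	NA	NA	TRUE	bound	canonical	NA	KAR1-17g:-130:mutA/C	synthetic-probe;provisional-18th
KAR2-10g	+	CTTTAGGTTATATCG	-153	-139	FALSE	TRUE	bound	insertion	4	NA	-
KAR2-10g	+	CTTCAGGTTATATCG	NA	NA	NA	TRUE	bound	insertion	4	KAR2-10g:-153:mutT/C	synthetic-probe
ENR2-16g	+	CATCGTTTTGATCG	-997	-984	TRUE	TRUE	smear	canonical	NA	NA	-
ENR2-16g	-	CTTTGTGAGGGCCG	-1020	-1007	TRUE	TRUE	smear	canonical	NA	NA	-
ENR2-16g	-	CTTTGGAAGTATCG	-1042	-1029	TRUE	TRUE	smear	canonical	NA	NA	-
ENR-17g	+	CTTTGTTTTAATCG	-644	-631	TRUE	TRUE	smear	canonical	NA	NA	-
ENR-17g	-	CTTTGTGAGGGCCG	-677	-664	TRUE	TRUE	smear	canonical	NA	NA	-
ENR-17g	-	CTTTGGAAGTATCG	-699	-686	TRUE	TRUE	smear	canonical	NA	NA	-
FATA1-1g	+	CCTCGTGCATATCG	-110	-97	TRUE	TRUE	bound	canonical	NA	NA	-
FATA1-1g	+	CGTCGCGTCGCGCG	-900	-887	FALSE	TRUE	unbound	canonical	NA	NA	-
FATB1-6g	+	CGTCGCTGTTTCCG	23	36	FALSE	TRUE	unbound	canonical	NA	NA	downstream-of-TIS
FATB1-6g	-	CCTTGCTTGCCTCG	-1419	-1406	FALSE	TRUE	unbound	canonical	NA	NA	tested-inferred
FATB-9g	-	CGTTGAACGGAACG	-2174	-2161	FALSE	TRUE	unbound	canonical	NA	NA	tested-inferred
FATB-9g	-	CTTCGTTTGGATCG	-2357	-2344	FALSE	TRUE	unbound	canonical	NA	NA	-
FATB-9g	-	CTTCGTCTCCGTCG	-2375	-2362	FALSE	TRUE	unbound	canonical	NA	NA	tested-inferred
SAD17-1g	-	CCTTGTGAGAATCG	-610	-597	FALSE	TRUE	unbound	canonical	NA	NA	-
SAD17-1g	-	CCTTGATATCATCG	-1159	-1146	FALSE	FALSE	untested	canonical	NA	NA	-
SAD6-11g	+	CATAGGCAACTTACG	-670	-656	FALSE	TRUE	unbound	insertion	NA	NA	extra-base
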