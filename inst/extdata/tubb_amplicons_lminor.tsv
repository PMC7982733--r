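clone	locus	region	predicted	detected	detected_all	intron	allelic_variant
8627	TUBB 1-1	intron1	600	598	598	295	FALSE
8627	TUBB 1-1	intron2	301	299	299	69	FALSE
8627	TUBB 4-1	intron1	600	598	598	295	FALSE
8627	TUBB 4-1	intron2	302	301	301	70	FALSE
8627	TUBB 13-1	intron1	364	361	361/364	59	TRUE
8627	TUBB 13-1	intron2	304	302	302	72	FALSE
8627	TUBB 29-1	intron1	388	385	385	83	FALSE
8627	TUBB 29-1	intron2	304	302	302	72	FALSE
8627	TUBB 11-1	intron1	756	757	757	451	FALSE
8627	TUBB 11-1	intron2	302	301	301	70	FALSE
8627	TUBB 11-2	intron1	376	375	375	71	FALSE
8627	TUBB 11-2	intron2	503	503	503	271	FALSE
8627	TUBB 23-1	intron1	729	730	730	424	FALSE
8627	TUBB 23-1	intron2	302	301	301	70	FALSE
8627	TUBB 23-2	intron1	379	377	377	74	FALSE
8627	TUBB 23-2	intron2	501	503	503	269	FALSE
8627	TUBB 26-1	intron1	401	398	398	96	FALSE
8627	TUBB 26-1	intron2	296	294	294	64	FALSE
8627	TUBB 26-2	intron1	742	742	742	437	FALSE
8627	TUBB 26-2	intron2	948	947	947	716	FALSE
8627	TUBB 39-1	intron1	397	395	395	92	FALSE
8627	TUBB 39-1	intron2	297	298	298	65	FALSE
8627	TUBB 39-2	intron1	824	822	822	519	FALSE
8627	TUBB 39-2	intron2	827	825	825	595	FALSE
5500	contig6002:4667-6360	intron1	600	598	598	295	FALSE
5500	contig6002:4667-6360	intron2	302	301	301	70	FALSE
5500	contig4882:16737-18430	intron1	600	598	598	295	FALSE
5500	contig4882:16737-18430	intron2	302	301	301	70	FALSE
5500	contig10021:2826-4519	intron1	600	598	598	295	FALSE
5500	contig10021:2826-4519	intron2	302	301	301	70	FALSE
5500	contig5070:18395-20056rw	intron1	379	377	377	74	FALSE
5500	contig5070:18395-20056rw	intron2	501	503	503	269	FALSE
5500	contig9243:5991-7483rw	intron1	397	395	395	92	FALSE
5500	contig9243:5991-7483rw	intron2	297	298	298	65	FALSE
5500	contig6970:2575-4405rw	intron1	729	730	730	424	FALSE
5500	contig6970:2575-4405rw	intron2	302	301	301	70	FALSE
5500	contig2456:16516-18911rw	intron1	824	822	822	519	FALSE
5500	contig2456:16516-18911rw	intron2	827	825	825	595	FALSE
5500	contig3435:26387-27804	intron1	376	367	367/373	71	TRUE
5500	contig3435:26387-27804	intron2	304	302	302	72	FALSE
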