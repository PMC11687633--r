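# Synthetic oxy/deoxy hemoglobin molar extinction table (version 1.0)
# Gaussian-band parameterization emulating the canonical compilations:
# Soret tail, HbO2 beta/alpha bands (542/576 nm), Hb band near 555 nm,
# isosbestic crossings engineered near 522/545/570/584 nm.
# Units: wavelength nm; extinction cm^-1 (mol/L)^-1, base-10 convention.
# NOT measured data: constructed for self-consistent simulation/recovery.
wavelength_nm	eps_hb	eps_hbo2
400	56505.5	35277.0
401	58064.2	36128.3
402	59612.1	36970.4
403	61146.0	37801.8
404	62662.6	38620.8
405	64158.5	39425.8
406	65630.4	40215.2
407	67074.9	40987.3
408	68488.6	41740.6
409	69868.2	42473.5
410	71210.2	43184.4
411	72511.3	43871.7
412	73768.4	44533.9
413	74978.1	45169.6
414	76137.4	45777.4
415	77243.3	46355.9
416	78292.7	46903.7
417	79283.0	47419.5
418	80211.4	47902.3
419	81075.4	48350.8
420	81872.6	48764.0
421	82600.9	49140.9
422	83258.1	49480.7
423	83842.5	49782.4
424	84352.4	50045.4
425	84786.3	50269.0
426	85143.0	50452.7
427	85421.5	50596.1
428	85621.1	50698.7
429	85741.0	50760.4
430	85781.0	50781.0
431	85741.0	50760.4
432	85621.1	50698.7
433	85421.6	50596.1
434	85143.0	50452.7
435	84786.3	50269.0
436	84352.4	50045.4
437	83842.5	49782.4
438	83258.2	49480.7
439	82601.0	49140.9
440	81872.7	48764.0
441	81075.5	48350.8
442	80211.5	47902.3
443	79283.1	47419.5
444	78292.9	46903.7
445	77243.5	46355.9
446	76137.6	45777.4
447	74978.4	45169.6
448	73768.7	44533.9
449	72511.7	43871.7
450	71210.6	43184.4
451	69868.6	42473.5
452	68489.2	41740.6
453	67075.6	40987.3
454	65631.3	40215.2
455	64159.5	39425.8
456	62663.8	38620.8
457	61147.6	37801.8
458	59614.1	36970.4
459	58066.7	36128.3
460	56508.7	35277.0
461	54943.3	34418.1
462	53373.7	33553.2
463	51803.0	32683.9
464	50234.1	31811.6
465	48670.1	30937.9
466	47113.7	30064.2
467	45567.7	29191.9
468	44034.9	28322.4
469	42517.7	27456.9
470	41018.6	26596.8
471	39540.1	25743.2
472	38084.4	24897.4
473	36653.7	24060.4
474	35250.3	23233.2
475	33876.2	22416.8
476	32533.4	21612.2
477	31223.9	20820.3
478	29949.5	20041.7
479	28712.2	19277.3
480	27513.8	18527.7
481	26356.1	17793.6
482	25240.8	17075.5
483	24169.7	16373.8
484	23144.5	15689.1
485	22166.8	15021.7
486	21238.2	14371.8
487	20360.3	13739.9
488	19534.4	13126.0
489	18761.8	12530.4
490	18043.7	11953.3
491	17380.9	11394.6
492	16774.0	10854.5
493	16223.4	10333.0
494	15728.8	9830.2
495	15289.9	9346.1
496	14905.5	8880.9
497	14574.0	8434.7
498	14293.2	8007.7
499	14060.1	7600.4
500	13871.2	7213.3
501	13722.3	6847.3
502	13608.5	6503.4
503	13524.2	6183.2
504	13463.5	5888.6
505	13420.1	5622.4
506	13387.5	5387.9
507	13359.4	5189.1
508	13329.8	5031.1
509	13293.2	4920.3
510	13245.5	4863.9
511	13183.5	4870.5
512	13106.2	4950.2
513	13014.5	5114.1
514	12911.7	5374.8
515	12803.9	5746.0
516	12700.2	6242.1
517	12612.4	6878.3
518	12555.4	7669.8
519	12546.7	8631.6
520	12606.2	9777.5
521	12755.7	11119.5
522	13017.8	12667.2
523	13415.7	14426.6
524	13971.8	16399.3
525	14706.6	18582.1
526	15638.1	20965.6
527	16780.0	23534.0
528	18141.3	26264.8
529	19725.2	29128.1
530	21528.3	32087.6
531	23540.3	35100.1
532	25743.7	38117.0
533	28114.0	41085.1
534	30620.0	43947.8
535	33224.8	46647.4
536	35886.3	49126.4
537	38558.9	51329.6
538	41194.7	53206.6
539	43745.1	54712.8
540	46162.3	55812.4
541	48400.8	56478.8
542	50418.7	56696.8
543	52179.7	56462.6
544	53653.2	55785.1
545	54816.0	54685.1
546	55652.7	53195.3
547	56156.2	51359.7
548	56328.0	49231.9
549	56178.3	46874.4
550	55725.8	44356.2
551	54997.5	41751.8
552	54028.4	39139.0
553	52860.8	36596.9
554	51543.1	34204.2
555	50129.5	32037.0
556	48678.1	30167.0
557	47249.2	28659.2
558	45903.8	27570.2
559	44700.9	26945.8
560	43695.2	26818.9
561	42934.2	27207.8
562	42455.8	28114.2
563	42285.1	29521.7
564	42433.0	31395.3
565	42893.9	33680.5
566	43644.9	36304.8
567	44646.2	39178.1
568	45841.8	42196.6
569	47162.2	45245.2
570	48527.4	48202.9
571	49851.1	50947.4
572	51045.7	53361.3
573	52027.3	55337.4
574	52720.6	56784.3
575	53063.6	57630.8
576	53011.4	57830.1
577	52538.4	57361.3
578	51640.0	56230.9
579	50331.9	54471.1
580	48648.7	52138.1
581	46641.0	49307.8
582	44371.8	46071.4
583	41911.8	42530.0
584	39335.2	38788.8
585	36714.8	34951.9
586	34118.0	31117.5
587	31603.8	27373.3
588	29220.6	23794.2
589	27004.1	20440.1
590	24977.8	17354.9
591	23152.8	14567.1
592	21529.6	12090.6
593	20099.5	9926.7
594	18846.7	8065.8
595	17750.6	6490.2
596	16787.9	5176.5
597	15934.5	4097.3
598	15167.1	3223.7
599	14464.3	2526.8
600	13807.7	1978.7
601	13182.0	1553.6
602	12575.6	1228.6
603	11980.4	983.5
604	11391.2	801.1
605	10805.7	667.4
606	10223.6	570.5
607	9646.5	501.4
608	9077.0	452.6
609	8518.5	418.7
610	7974.9	395.5
611	7449.8	379.7
612	6946.8	369.2
613	6468.9	362.2
614	6018.8	357.7
615	5598.5	354.8
616	5209.1	353.0
617	4851.6	351.8
618	4526.0	351.1
619	4232.1	350.7
620	3969.1	350.4
621	3735.7	350.2
622	3530.8	350.1
623	3352.4	350.1
624	3199.0	350.0
625	3068.6	350.0
626	2959.3	350.0
627	2869.1	350.0
628	2796.3	350.0
629	2738.9	350.0
630	2695.2	350.0
631	2663.8	350.0
632	2642.9	350.0
633	2631.4	350.0
634	2627.8	350.0
635	2631.2	350.0
636	2640.4	350.0
637	2654.6	350.0
638	2673.1	350.0
639	2695.0	350.0
640	2719.8	350.0
641	2747.0	350.0
642	2776.2	350.0
643	2806.8	350.0
644	2838.7	350.0
645	2871.4	350.0
646	2904.8	350.0
647	2938.7	350.0
648	2972.9	350.0
649	3007.2	350.0
650	3041.5	350.0
651	3075.7	350.0
652	3109.7	350.0
653	3143.4	350.0
654	3176.8	350.0
655	3209.7	350.0
656	3242.2	350.0
657	3274.1	350.0
658	3305.5	350.0
659	3336.3	350.0
660	3366.5	350.0
661	3396.0	350.0
662	3424.8	350.0
663	3452.8	350.0
664	3480.1	350.0
665	3506.5	350.0
666	3532.2	350.0
667	3557.0	350.0
668	3580.9	350.0
669	3604.0	350.0
670	3626.1	350.0
671	3647.3	350.0
672	3667.5	350.0
673	3686.7	350.0
674	3705.0	350.0
675	3722.2	350.0
676	3738.4	350.0
677	3753.6	350.0
678	3767.7	350.0
679	3780.7	350.0
680	3792.6	350.0
681	3803.5	350.0
682	3813.2	350.0
683	3821.8	350.0
684	3829.2	350.0
685	3835.6	350.0
686	3840.8	350.0
687	3844.8	350.0
688	3847.7	350.0
689	3849.4	350.0
690	3850.0	350.0
691	3849.4	350.0
692	3847.7	350.0
693	3844.8	350.0
694	3840.8	350.0
695	3835.6	350.0
696	3829.2	350.0
697	3821.8	350.0
698	3813.2	350.0
699	3803.5	350.0
700	3792.6	350.0
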