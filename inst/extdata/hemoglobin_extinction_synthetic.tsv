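# Synthetic hemoglobin molar extinction table (parametric approximation).
# Columns: wavelength_nm, eps_HbO2, eps_dHb; units cm^-1 M^-1.
# Band positions/magnitudes match published values (HbO2 542/577 nm, dHb ~556 nm);
# shapes are analytic (Gaussian bands + Soret tail), NOT digitized measurements.
wavelength_nm	eps_HbO2	eps_dHb
450.0	65077.8	101031.6
451.0	62051.5	98831.8
452.0	59077.1	96585.6
453.0	56161.3	94300.0
454.0	53310.2	91981.9
455.0	50529.2	89638.0
456.0	47823.2	87274.9
457.0	45196.5	84899.3
458.0	42652.5	82517.4
459.0	40194.5	80135.6
460.0	37824.9	77759.7
461.0	35545.6	75395.4
462.0	33357.8	73048.3
463.0	31262.6	70723.5
464.0	29260.2	68426.0
465.0	27350.6	66160.3
466.0	25533.2	63930.6
467.0	23807.2	61741.0
468.0	22171.4	59595.2
469.0	20624.0	57496.3
470.0	19163.3	55447.4
471.0	17787.1	53451.1
472.0	16493.1	51509.7
473.0	15278.7	49625.3
474.0	14141.2	47799.4
475.0	13077.7	46033.6
476.0	12085.4	44328.7
477.0	11161.1	42685.7
478.0	10301.8	41105.1
479.0	9504.4	39587.1
480.0	8765.7	38131.8
481.0	8082.7	36738.8
482.0	7452.4	35407.9
483.0	6871.5	34138.5
484.0	6337.3	32929.6
485.0	5846.8	31780.4
486.0	5397.1	30689.9
487.0	4985.7	29656.7
488.0	4609.8	28679.6
489.0	4267.0	27757.2
490.0	3954.9	26888.0
491.0	3671.2	26070.6
492.0	3413.9	25303.4
493.0	3180.9	24584.9
494.0	2970.5	23913.6
495.0	2780.9	23287.9
496.0	2610.7	22706.4
497.0	2458.6	22167.7
498.0	2323.7	21670.6
499.0	2205.0	21213.8
500.0	2102.1	20796.3
501.0	2014.8	20417.1
502.0	1943.6	20075.5
503.0	1889.0	19770.8
504.0	1852.4	19502.6
505.0	1835.9	19270.6
506.0	1842.1	19074.9
507.0	1874.7	18915.6
508.0	1938.3	18793.0
509.0	2038.5	18708.0
510.0	2182.3	18661.2
511.0	2377.8	18653.8
512.0	2634.3	18687.1
513.0	2962.7	18762.6
514.0	3374.8	18882.0
515.0	3883.8	19047.1
516.0	4503.6	19260.0
517.0	5248.7	19522.8
518.0	6133.9	19837.6
519.0	7173.3	20206.6
520.0	8380.5	20632.1
521.0	9767.1	21116.1
522.0	11342.3	21660.6
523.0	13112.2	22267.3
524.0	15078.6	22937.6
525.0	17238.6	23672.6
526.0	19583.6	24473.1
527.0	22098.8	25339.2
528.0	24763.1	26270.5
529.0	27548.5	27265.9
530.0	30420.4	28323.9
531.0	33338.4	29441.7
532.0	36256.4	30616.3
533.0	39124.1	31843.4
534.0	41888.1	33118.2
535.0	44493.8	34434.6
536.0	46886.8	35786.2
537.0	49015.1	37165.2
538.0	50830.9	38563.5
539.0	52292.5	39971.9
540.0	53365.9	41380.7
541.0	54026.6	42779.7
542.0	54260.4	44158.0
543.0	54064.2	45504.7
544.0	53446.9	46808.3
545.0	52428.7	48057.6
546.0	51041.2	49241.4
547.0	49326.4	50348.7
548.0	47335.3	51368.9
549.0	45127.2	52292.1
550.0	42767.2	53109.1
551.0	40325.2	53811.5
552.0	37873.6	54392.0
553.0	35485.8	54844.4
554.0	33233.8	55163.9
555.0	31187.2	55346.7
556.0	29410.5	55390.6
557.0	27962.0	55294.9
558.0	26892.1	55060.2
559.0	26241.3	54688.4
560	26039	54183
561.0	26302.0	53548.8
562.0	27033.6	52791.7
563.0	28222.0	51918.8
564.0	29840.4	50938.3
565.0	31846.5	49859.1
566	34183	48691
567.0	36778.7	47444.3
568.0	39550.2	46129.8
569.0	42404.3	44758.4
570.0	45241.4	43341.1
571.0	47958.8	41889.1
572.0	50454.8	40413.1
573.0	52633.3	38923.6
574.0	54407.4	37430.6
575.0	55703.9	35943.4
576.0	56466.4	34470.9
577.0	56657.5	33020.9
578.0	56260.9	31600.8
579.0	55281.4	30216.8
580.0	53744.5	28874.3
581.0	51694.7	27578.0
582.0	49192.5	26331.5
583.0	46311.1	25137.6
584.0	43132.8	23998.4
585.0	39744.4	22915.2
586.0	36233.3	21888.4
587.0	32683.6	20917.9
588.0	29173.0	20002.9
589.0	25769.9	19142.4
590.0	22531.5	18334.4
591.0	19503.0	17577.1
592.0	16717.3	16867.9
593.0	14194.9	16204.3
594.0	11945.4	15583.5
595.0	9968.5	15002.6
596.0	8255.7	14458.6
597.0	6792.4	13948.6
598.0	5559.0	13469.7
599.0	4533.2	13019.0
600.0	3691.1	12593.7
601.0	3008.7	12191.4
602.0	2462.5	11809.5
603.0	2030.7	11445.9
604.0	1693.5	11098.3
605.0	1433.2	10765.0
606.0	1234.6	10444.2
607.0	1084.6	10134.4
608.0	972.5	9834.3
609.0	889.5	9542.7
610.0	828.5	9258.7
611.0	783.9	8981.5
612.0	751.5	8710.4
613.0	727.9	8444.8
614.0	710.6	8184.4
615.0	697.9	7928.8
616.0	688.3	7677.8
617.0	680.8	7431.4
618.0	674.9	7189.3
619.0	670.0	6951.7
620.0	665.8	6718.5
621.0	662.0	6489.9
622.0	658.5	6265.9
623.0	655.2	6046.6
624.0	652.1	5832.3
625.0	649.1	5622.9
626.0	646.1	5418.7
627.0	643.2	5219.7
628.0	640.4	5026.2
629.0	637.5	4838.1
630.0	634.7	4655.6
631.0	631.9	4478.6
632.0	629.2	4307.4
633.0	626.4	4141.9
634.0	623.7	3982.1
635	621	3828
636.0	618.4	3679.6
637.0	615.7	3536.9
638.0	613.1	3399.7
639.0	610.5	3268.0
640.0	607.9	3141.8
641.0	605.4	3020.9
642.0	602.8	2905.2
643.0	600.3	2794.5
644.0	597.8	2688.9
645.0	595.4	2588.1
646.0	592.9	2492.0
647.0	590.5	2400.4
648.0	588.1	2313.2
649.0	585.7	2230.3
650.0	583.3	2151.4
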