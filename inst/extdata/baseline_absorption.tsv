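# Non-melanin baseline tissue absorption shape: (lambda/500)^-3.255, cm^-1
# scaled at fit time by the dimensionless baseline parameter s_base.
wavelength_nm	mua_base
450.000000	1.409096
451.000000	1.398952
452.000000	1.388902
453.000000	1.378947
454.000000	1.369085
455.000000	1.359315
456.000000	1.349636
457.000000	1.340047
458.000000	1.330547
459.000000	1.321135
460.000000	1.311809
461.000000	1.302569
462.000000	1.293414
463.000000	1.284344
464.000000	1.275356
465.00000	1.26645
466.000000	1.257625
467.000000	1.248881
468.000000	1.240215
469.000000	1.231629
470.000000	1.223119
471.000000	1.214687
472.00000	1.20633
473.000000	1.198048
474.000000	1.189841
475.000000	1.181707
476.000000	1.173645
477.000000	1.165655
478.000000	1.157736
479.000000	1.149887
480.000000	1.142108
481.000000	1.134397
482.000000	1.126754
483.000000	1.119179
484.00000	1.11167
485.000000	1.104226
486.000000	1.096848
487.000000	1.089533
488.000000	1.082283
489.000000	1.075095
490.00000	1.06797
491.000000	1.060906
492.000000	1.053904
493.000000	1.046961
494.000000	1.040079
495.000000	1.033255
496.00000	1.02649
497.000000	1.019782
498.000000	1.013132
499.000000	1.006538
500	1
501.0000000	0.9935176
502.00000	0.98709
503.0000000	0.9807167
504.0000000	0.9743971
505.0000000	0.9681306
506.0000000	0.9619166
507.0000000	0.9557547
508.0000000	0.9496443
509.0000000	0.9435849
510.0000000	0.9375759
511.0000000	0.9316169
512.0000000	0.9257072
513.0000000	0.9198465
514.0000000	0.9140341
515.0000000	0.9082697
516.0000000	0.9025527
517.0000000	0.8968827
518.0000000	0.8912591
519.0000000	0.8856816
520.0000000	0.8801496
521.0000000	0.8746626
522.0000000	0.8692203
523.0000000	0.8638222
524.0000000	0.8584678
525.0000000	0.8531568
526.0000000	0.8478885
527.0000000	0.8426628
528.000000	0.837479
529.0000000	0.8323369
530.000000	0.827236
531.0000000	0.8221758
532.0000000	0.8171561
533.0000000	0.8121763
534.0000000	0.8072361
535.0000000	0.8023351
536.000000	0.797473
537.0000000	0.7926493
538.0000000	0.7878636
539.0000000	0.7831157
540.0000000	0.7784051
541.0000000	0.7737315
542.0000000	0.7690945
543.0000000	0.7644937
544.0000000	0.7599289
545.0000000	0.7553996
546.0000000	0.7509056
547.0000000	0.7464464
548.0000000	0.7420218
549.0000000	0.7376314
550.0000000	0.7332749
551.000000	0.728952
552.0000000	0.7246623
553.0000000	0.7204056
554.0000000	0.7161815
555.0000000	0.7119897
556.0000000	0.7078299
557.0000000	0.7037019
558.0000000	0.6996052
559.0000000	0.6955397
560.000000	0.691505
561.0000000	0.6875009
562.000000	0.683527
563.000000	0.679583
564.0000000	0.6756688
565.000000	0.671784
566.0000000	0.6679284
567.0000000	0.6641016
568.0000000	0.6603034
569.0000000	0.6565336
570.0000000	0.6527918
571.0000000	0.6490779
572.0000000	0.6453916
573.0000000	0.6417325
574.0000000	0.6381006
575.0000000	0.6344955
576.0000000	0.6309169
577.0000000	0.6273647
578.0000000	0.6238386
579.0000000	0.6203384
580.0000000	0.6168637
581.0000000	0.6134145
582.0000000	0.6099905
583.0000000	0.6065914
584.000000	0.603217
585.0000000	0.5998671
586.0000000	0.5965415
587.0000000	0.5932399
588.0000000	0.5899622
589.0000000	0.5867081
590.0000000	0.5834774
591.00000	0.58027
592.0000000	0.5770856
593.0000000	0.5739239
594.0000000	0.5707849
595.0000000	0.5676683
596.0000000	0.5645739
597.0000000	0.5615015
598.0000000	0.5584509
599.000000	0.555422
600.0000000	0.5524145
601.0000000	0.5494282
602.000000	0.546463
603.0000000	0.5435187
604.0000000	0.5405951
605.0000000	0.5376921
606.0000000	0.5348093
607.0000000	0.5319468
608.0000000	0.5291042
609.0000000	0.5262815
610.0000000	0.5234784
611.0000000	0.5206948
612.0000000	0.5179305
613.0000000	0.5151854
614.0000000	0.5124592
615.0000000	0.5097519
616.0000000	0.5070633
617.0000000	0.5043931
618.0000000	0.5017413
619.0000000	0.4991077
620.0000000	0.4964922
621.0000000	0.4938945
622.0000000	0.4913146
623.0000000	0.4887522
624.0000000	0.4862074
625.0000000	0.4836798
626.0000000	0.4811693
627.0000000	0.4786759
628.0000000	0.4761993
629.0000000	0.4737394
630.0000000	0.4712961
631.0000000	0.4688693
632.0000000	0.4664588
633.0000000	0.4640644
634.0000000	0.4616861
635.0000000	0.4593237
636.0000000	0.4569771
637.0000000	0.4546461
638.0000000	0.4523307
639.0000000	0.4500306
640.0000000	0.4477458
641.0000000	0.4454762
642.0000000	0.4432215
643.0000000	0.4409818
644.0000000	0.4387568
645.0000000	0.4365465
646.0000000	0.4343507
647.0000000	0.4321693
648.0000000	0.4300022
649.0000000	0.4278494
650.0000000	0.4257105
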