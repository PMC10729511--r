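##TITLE=synthetic glass flow cell + glucose demo spectrum
##JCAMP-DX=4.24
##DATA TYPE=RAMAN SPECTRUM
##XUNITS=1/CM
##YUNITS=ARBITRARY UNITS
##XFACTOR=1
##YFACTOR=1
##FIRSTX=1800
##LASTX=650
##NPOINTS=51
##XYPOINTS=(XY..XY)
1800, 3.0169e-49
1777, 2.28382e-46
1754, 1.41024e-43
1731, 7.10323e-41
1708, 2.91843e-38
1685, 9.78075e-36
1662, 2.67379e-33
1639, 5.96227e-31
1616, 1.08449e-28
1593, 1.60906e-26
1570, 3.88047e-24
1547, 8.45312e-16
1524, 3.38414e-09
1501, 0.000124035
1478, 0.0416204
1455, 0.12786
1432, 0.00359607
1409, 1.78728e-05
1386, 0.00400798
1363, 0.086456
1340, 0.170098
1317, 0.0305238
1294, 0.000501999
1271, 2.14536e-05
1248, 0.00014469
1225, 0.000824662
1202, 0.00383392
1179, 0.0145655
1156, 0.0558511
1133, 0.285911
1110, 0.341023
1087, 0.474844
1064, 0.776475
1041, 0.665052
1018, 0.54823
995, 0.40628
972, 0.246317
949, 0.121814
926, 0.0491446
903, 0.0164524
880, 0.0115734
857, 0.0828498
834, 0.410699
811, 0.911045
788, 0.895028
765, 0.389283
742, 0.0749578
719, 0.00638986
696, 0.000241151
673, 4.0291e-06
650, 2.98024e-08
##END=
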