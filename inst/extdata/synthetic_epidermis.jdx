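##TITLE=synthetic normal-epidermis Amide I trace (package example)
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=1/CM
##YUNITS=ABSORBANCE
##XFACTOR=1
##YFACTOR=0.0001
##FIRSTX=1585
##LASTX=1710
##NPOINTS=11
##XYPOINTS=(XY..XY)
1585, 412
1597, 1181
1610, 2718
1622, 5103
1635, 7754
1647, 9570
1660, 9417
1672, 7424
1685, 4923
1697, 3823
1710, 2706
##END=
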