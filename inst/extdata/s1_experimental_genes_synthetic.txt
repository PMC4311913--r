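# Synthetic stand-in fixture: structure mirrors the published supplementary material; identifiers are invented.
ENSP90007547633
ENSP90005832568
ENSP90003326337
ENSP90006027827
ENSP90008869890
ENSP90005569407
ENSP90005745859
ENSP90006222171
ENSP90008065919
ENSP90003884056
ENSP90005813132
ENSP90008847548
ENSP90002146324
ENSP90005265041
ENSP90007861797
ENSP90007583880
ENSP90001977213
ENSP90000735731
ENSP90001966792
ENSP90004691997
ENSP90003544651
ENSP90004026230
ENSP90002697490
ENSP90007085335
ENSP90007847357
ENSP90001691566
ENSP90005669286
ENSP90007093446
ENSP90004303951
ENSP90001449970
ENSP90001695916
ENSP90007395055
ENSP90007694661
ENSP90007044791
ENSP90006488362
ENSP90003148927
ENSP90006554199
ENSP90000257611
ENSP90007664023
ENSP90003625126
ENSP90007429867
ENSP90008418794
ENSP90007784599
ENSP90006962275
ENSP90007014897
ENSP90005704823
ENSP90002370365
ENSP90005787333
ENSP90007894745
ENSP90002447457
ENSP90007736204
ENSP90008711291
ENSP90006129493
ENSP90004942971
ENSP90005356167
ENSP90006753666
ENSP90004756880
ENSP90006395697
ENSP90008596148
ENSP90007434352
ENSP90000731552
ENSP90007815290
ENSP90000893582
ENSP90006558960
ENSP90006309731
ENSP90000353219
ENSP90007760527
ENSP90004785976
ENSP90005347391
ENSP90002099742
ENSP90008285917
ENSP90005815864
ENSP90001018024
ENSP90001417606
ENSP90001129100
ENSP90001532547
ENSP90003367558
ENSP90005417744
ENSP90000872159
ENSP90005577315
ENSP90006740149
ENSP90004189390
ENSP90000530680
ENSP90002732584
ENSP90004889926
ENSP90001997712
ENSP90002117548
ENSP90006950436
ENSP90001355144
ENSP90002424459
ENSP90007270054
ENSP90008202620
ENSP90008294566
ENSP90002017793
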