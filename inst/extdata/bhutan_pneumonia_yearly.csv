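year,age_group,cases,population
2010,under5,9204,53147
2011,under5,7975,53740
2012,under5,9939,54337
2013,under5,8956,54942
2014,under5,9434,55553
2015,under5,7489,56171
2016,under5,8150,56795
2017,under5,5883,57427
2018,under5,4777,58059
2010,5to14,1383,122183
2011,5to14,1300,123542
2012,5to14,1469,124916
2013,5to14,1336,126305
2014,5to14,1517,127710
2015,5to14,1204,129131
2016,5to14,1293,130567
2017,5to14,1123,132019
2018,5to14,883,133471
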