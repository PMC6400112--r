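region,year,age_group,count,printed_ratio
World,2010,all,6958169,NA
World,2030,all,8551199,1.229
World,2010,60+,769413,NA
World,2030,60+,1406105,1.828
World,2010,80+,106575,NA
World,2030,80+,201868,1.894
High-income countries,2010,all,1148592,NA
High-income countries,2030,all,1249896,1.088
High-income countries,2010,60+,241336,NA
High-income countries,2030,60+,359030,1.488
High-income countries,2010,80+,47618,NA
High-income countries,2030,80+,83047,1.744
Other,2010,all,5809577,NA
Other,2030,all,7301302,1.257
Other,2010,60+,528077,NA
Other,2030,60+,1047075,1.983
Other,2010,80+,58958,NA
Other,2030,80+,118821,2.015
China,2010,all,1359755,NA
China,2030,all,1441182,1.060
China,2010,60+,171120,NA
China,2030,60+,361620,2.113
China,2010,80+,18777,NA
China,2030,80+,40843,2.175
Canada,2010,all,34169,NA
Canada,2030,all,40618,1.189
Canada,2010,60+,6819,NA
Canada,2030,60+,11849,1.738
Canada,2010,80+,1345,NA
Canada,2030,80+,2606,1.937
USA,2010,all,308641,NA
USA,2030,all,354712,1.149
USA,2010,60+,56707,NA
USA,2030,60+,91720,1.617
USA,2010,80+,11170,NA
USA,2030,80+,19274,1.726
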