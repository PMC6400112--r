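region,age_group,year,count
World,60-79,2010,5470
World,60-79,2020,7247
World,60-79,2030,10083
World,60+,2010,10124
World,60+,2020,13927
World,60+,2030,19195
High-income countries,60-79,2010,1622
High-income countries,60-79,2020,2014
High-income countries,60-79,2030,2440
High-income countries,60+,2010,4046
High-income countries,60+,2020,5302
High-income countries,60+,2030,6813
Other,60-79,2010,4010
Other,60-79,2020,5523
Other,60-79,2030,7981
Other,60+,2010,5726
Other,60+,2020,8082
Other,60+,2030,11523
China,60-79,2010,1195
China,60-79,2020,1709
China,60-79,2030,2542
China,60+,2010,1636
China,60+,2020,2365
China,60+,2030,3512
Canada,60-79,2010,43
Canada,60-79,2020,62
Canada,60-79,2030,81
Canada,60+,2010,95
Canada,60+,2020,131
Canada,60+,2030,183
USA,60-79,2010,363
USA,60-79,2020,510
USA,60-79,2030,645
USA,60+,2010,813
USA,60+,2020,1045
USA,60+,2030,1412
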