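community,n_hospitals,total_fragmented,previous_within
East Anglia,10,537408,385490
Merseyside,12,1002066,888043
North East,9,1086068,1024145
North London,24,3373655,2696511
North West,15,1476174,1283869
South,16,1157703,754640
South London and South East,16,2107474,1567297
South West,16,1172622,986142
West Midlands,16,1343370,1137792
Yorkshire and North Midlands,21,1492251,1256115
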