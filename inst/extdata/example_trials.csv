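infant_id,occasion,trial,d
2523,3,1,-117
2523,3,2,120
2523,3,3,-124
2523,3,4,130
2523,3,5,97
2523,3,6,112
2523,3,7,-108
2523,3,8,126
2523,3,9,-130
2523,3,10,-34
2523,3,11,-122
2523,3,12,129
2523,3,13,129
2523,3,14,-76
2523,3,15,103
2523,3,16,-103
2523,3,17,0
2523,3,18,0
2523,3,19,-117
2523,3,20,130
2523,3,21,-112
2523,3,22,-108
2523,3,23,115
2523,3,24,0
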