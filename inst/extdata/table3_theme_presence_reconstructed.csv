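location,year,song_type_tag,recording_id,themes
NewZealand,2016,STB,pooled,1 2 3 4 5
NewZealand,2016,CS,pooled,1 2 3 4 5
NewZealand,2016,CS_9Aug,pooled,5 6 7 8
NewCaledonia,2015,A,pooled,12 13 14 15 16
NewCaledonia,2015,B,pooled,5 6 8
NewCaledonia,2016,,pooled,1 2 3 4 5 6 8
NewCaledonia,2017,,pooled,3 9 10 11
EastAustralia,2015,north,pooled,5 6 8
EastAustralia,2015,south,pooled,1 2 3 4 5
EastAustralia,2016,south,pooled,3 9 10 11
EastAustralia,2017,north,pooled,3 9 10 11
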