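year,rate,total
2014,0,
2015,0,
2016,0,
2017,0,
2018,0.629,
2019,0.374,
2020,0.082,
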