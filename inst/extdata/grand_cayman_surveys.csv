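year,mean,se
2014,254162,105725
2015,408749,161343
2016,814855,331218
2017,1060687,353234
2018,1319939,252108
2019,103020,42925
2020,25259,9485
2021,87751,34706
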