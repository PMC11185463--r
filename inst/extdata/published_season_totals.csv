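season,lo95,median,hi95
2017,377,532,715
2018,402,531,709
2019,312,455,661
2020,232,303,405
2021,347,437,553
2022,299,362,450
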