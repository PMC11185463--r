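season,beginning,peak,end
2017,2017-11-02,2017-12-30,2018-03-27
2018,2018-11-04,2019-01-01,2019-03-29
2019,2019-10-31,2019-12-28,2020-03-24
2020,2020-10-30,2020-12-27,2021-03-24
2021,2021-10-27,2021-12-24,2022-03-21
2022,2022-10-17,2022-12-14,2023-03-11
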