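>i29_seed1
WGYAVPPKYFTWWYDPYLAQFIPWQFPWVLEFMLAWPFTITSSMPDWMYQSWDFQYVEPYLP
>i29_seed2
WGYAVPMKNFTWTSDTYLAQFQPWQFPWVLEFMLAWPRTPTSSMPDWMYQSWDFQYVEPYLW
>i29_seed3
WGYNVPPKYFTWWYDPYLAQFIPWQFPWVLEFMLAWPFTITSSRPDWMYQSWDFQNVEQPPP
>i29_seed4
WGYAYLPKYFTLWYDPRLAQVIPWQFPQVLEFMHAWPFTITSMMPDCMQQSWDFQYVEPYLP
>i29_seed5
WGYAVPPKYFTWWYHGWLAQYVPWQDPWVLEFNLAGPFTITSSMPDWAYQSWHFQYVEPHLP
>i29_seed6
WGYAVPPKYATWRYDPFLAQFIPWQFPWVLEFMLAWPFTIMSSMPDWMYQSWGFQYVEPYLP
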