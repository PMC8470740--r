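>Tau1 tau 173-183 with flanking C/A and W for experimental labelling
CAKTPPAPKTPPAW
>Tau2 tau 225-246
KVAVVRTPPKSPSSAKSRLQTA
>bCPP beta-casein 1-25 phosphopeptide
RELEELNVPGEIVESLSSSEESITR
>Stath statherin, full length
DSSEEKFLRRIGRFGYGYGPYQPVPEQPLYPQPYQPQYQQYTF
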