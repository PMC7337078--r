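# Four-population split-and-migration admixture demography.
# Forward in time: population 1 (size N = 1000) splits off population 2;
# N generations later population 3 splits from population 2; after another
# N generations population 4 splits from population 3; for the final N
# generations populations 2 and 3 exchange migrants at per-capita rate 4/N.
# Times below are backward from sampling, in generations.
population	1	1000
population	2	1000
population	3	1000
population	4	1000
sample	1	2
sample	2	2
sample	3	2
sample	4	2
migration	2	3	0.004
migration	3	2	0.004
event	1000	migration_off	2	3
event	1000	merge	4	3
event	2000	merge	3	2
event	3000	merge	2	1
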