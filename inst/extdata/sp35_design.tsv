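replicate_id	group
NN1	NN
NN2	NN
NN3	NN
NN4	NN
NN5	NN
NA1	NA
NA2	NA
NA3	NA
NA4	NA
OA1	OA
OA2	OA
ON1	ON
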