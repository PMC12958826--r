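protein	label	phenotype
Ssy1	T382K	gain_of_function
Ssy1	V694F	gain_of_function
Ssy1	F333S	gain_of_function
Ssy1	S351T	gain_of_function
Ssy1	V354L	gain_of_function
Ssy1	F358L	gain_of_function
Ssy1	G790V	gain_of_function
Ssy1	T639I	hypo_responsive
Ptr3	T435K	gain_of_function
Ptr3	Q439R	gain_of_function
Ptr3	E522K	loss_of_function
Ptr3	T525A	loss_of_function
Ssy5	E131K	gain_of_function
Ssy5	F575V	gain_of_function
Ssy5	Q576P	gain_of_function
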