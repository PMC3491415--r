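chrBase	chr	base	strand	coverage	freqC	freqT
chr21.9764539	chr21	9764539	R	12	25	75
chr21.9764513	chr21	9764513	R	12	0	100
chr21.9820622	chr21	9820622	F	13	0	100
chr21.9837545	chr21	9837545	F	11	0	100
chr21.9849022	chr21	9849022	F	124	72.58	27.42
chr21.9853326	chr21	9853326	F	17	70.59	29.41
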