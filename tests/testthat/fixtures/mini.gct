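#1.2
2	2
Name	Description	s1	s2
gA	first gene	1.5	2.0
gB	second gene	3.0	4.0
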