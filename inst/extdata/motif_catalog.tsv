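motif	class	groups
TEY	canonical	A,B,C,D
TGY	canonical	A,B,C,D
TDY	canonical
TPY	canonical
TTY	novel	D
TIY	novel	D
TNY	novel	A,C
THY	novel	A,B
TSY	novel	A
KGY	novel	A,C
TQY	novel	B
SEY	novel	D
SDY	novel	D
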