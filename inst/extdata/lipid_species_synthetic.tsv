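name	class	formula	n_carbons
FA 16:0	FA	C16H32O2	16
FA 18:1	FA	C18H34O2	18
PC 34:1	PC	C42H82NO8P	42
PC 36:2	PC	C44H84NO8P	44
PE 34:2	PE	C39H74NO8P	39
PA 34:1	PA	C37H71O8P	37
PI 34:1	PI	C43H81O13P	43
SM d18:1/16:0	SM	C39H79N2O6P	39
Cer d18:1/16:0	Cer	C34H67NO3	34
HexCer d18:1/16:0	HexCer	C40H77NO8	40
LacCer d18:1/16:0	LacCer	C46H87NO13	46
TG 52:2	TG	C55H102O6	55
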