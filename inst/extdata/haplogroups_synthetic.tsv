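name	parent	diagnostics
rCRS		
K	rCRS	73G 146C 16224C 16311C
K1a1b1a	K	114T 150T 16234T
K2a2a1	K	152T 16093C 16291T
H	rCRS	263G 315.1C
H3p	H	200G 16128A 16316G
HV1b2	rCRS	208C 16067T 16355C
I	rCRS	199C 250T 16129G
I1c1a	I	203A 16148T 16172T
J	rCRS	295T 16069T 16126C
J1c14	J	228A 16145G 16261T
V	rCRS	72C 16298C
V7a	V	94A 16153A 16217C
X	rCRS	153G 16189C 16223C
X2b7	X	225A 16278T 16357C
U5	rCRS	16192T 16270T
U5a1	U5	16256T 16359C
U5b1b	U5	160C 16144C
T	rCRS	16294T 16296C
T2b	T	104T 16304C
H1	H	110A 16162G
W	rCRS	189G 204C 16292T
W6	W	239T 16325C
N1b	rCRS	145G 176C 16176A
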