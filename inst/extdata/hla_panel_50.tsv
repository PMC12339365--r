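allele	locus
A*01:01	A
A*02:01	A
A*02:05	A
A*02:12	A
A*03:01	A
A*11:01	A
A*23:01	A
A*24:02	A
A*30:01	A
A*31:01	A
A*31:08	A
A*34:01	A
A*33:03	A
A*68:01	A
B*07:02	B
B*08:01	B
B*08:02	B
B*13:01	B
B*15:01	B
B*15:02	B
B*15:03	B
B*18:01	B
B*27:01	B
B*27:05	B
B*27:02	B
B*35:01	B
B*35:02	B
B*35:08	B
B*39:06	B
B*40:01	B
B*40:06	B
B*40:10	B
B*41:01	B
B*44:02	B
B*46:01	B
B*48:03	B
B*50:01	B
B*51:01	B
B*52:01	B
B*54:01	B
B*56:01	B
B*57:01	B
B*58:01	B
C*03:04	C
C*04:01	C
C*06:02	C
C*07:01	C
C*07:02	C
C*08:02	C
C*12:03	C
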