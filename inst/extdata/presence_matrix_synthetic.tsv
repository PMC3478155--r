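family	hsa	mmu	gga	xtr	dre	fru	tni	cca	bfl	cin	spu	dme	cel
let-7	+	+	+	+	+	+	+	+	+	+	+	+	+
mir-124	+	+	+	+	+	+	+	+	-	+	-	+	+
mir-9	+	+	+	+	+	+	+	+	+	-	-	+	+
mir-137	+	+	+	+	+	+	+	+	-	-	-	+	+
mir-7	+	+	+	+	+	+	+	+	+	+	-	+	-
mir-306	-	-	-	-	+	-	-	+	-	-	-	+	-
mir-430	-	-	-	-	+	-	-	+	-	-	-	-	-
mir-727	-	-	-	-	+	+	-	+	-	-	-	-	-
mir-132	+	+	+	+	+	+	+	+	-	-	-	-	-
mir-212	+	+	+	-	+	+	+	+	-	-	-	-	-
mir-140	+	+	+	+	+	+	+	+	-	-	-	-	-
mir-150	+	+	+	-	+	+	+	+	-	-	-	-	-
mir-204	+	+	+	+	+	+	+	+	-	-	-	-	-
mir-22	+	+	+	+	+	+	+	+	-	-	-	-	-
mir-541	+	+	-	-	+	-	-	+	-	-	-	-	-
mir-3065	+	+	-	-	+	-	-	+	-	-	-	-	-
mir-28	+	+	+	-	+	-	-	+	-	-	-	-	-
mir-297	+	+	-	-	+	-	-	+	-	-	-	-	-
mir-467	-	+	-	-	+	-	-	+	-	-	-	-	-
mir-3529	+	-	-	-	+	-	-	+	-	-	-	-	-
mir-460	+	-	+	-	+	+	+	+	-	-	-	-	-
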