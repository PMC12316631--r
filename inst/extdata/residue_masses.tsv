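token	class	formula	mono_mass	ambiguity	canonical
Gly	internal	C2H3NO	57.021464		Gly
Ala	internal	C3H5NO	71.037114		Ala
Ser	internal	C3H5NO2	87.032028		Ser
Pro	internal	C5H7NO	97.052764		Pro
Aib	internal	C4H7NO	85.052764		Aib
Vxx	internal	C5H9NO	99.068414	Val,Iva	Vxx
Val	internal	C5H9NO	99.068414		Vxx
Iva	internal	C5H9NO	99.068414		Vxx
Lxx	internal	C6H11NO	113.084064	Leu,Ile	Lxx
Leu	internal	C6H11NO	113.084064		Lxx
Ile	internal	C6H11NO	113.084064		Lxx
Gln	internal	C5H8N2O2	128.058578		Gln
Glu	internal	C5H7NO3	129.042593		Glu
Phe	internal	C9H9NO	147.068414		Phe
Trp	internal	C11H10N2O	186.079313		Trp
Tyr	internal	C9H9NO2	163.063329		Tyr
Lxxol	amino_alcohol	C6H15NO	117.115364	Leuol,Ileol	Lxxol
Leuol	amino_alcohol	C6H15NO	117.115364		Lxxol
Ileol	amino_alcohol	C6H15NO	117.115364		Lxxol
Vxxol	amino_alcohol	C5H13NO	103.099714	Valol	Vxxol
Valol	amino_alcohol	C5H13NO	103.099714		Vxxol
Pheol	amino_alcohol	C9H13NO	151.099714		Pheol
Trpol	amino_alcohol	C11H14N2O	190.110613		Trpol
Alaol	amino_alcohol	C3H9NO	75.068414		Alaol
Glyol	amino_alcohol	C2H7NO	61.052764		Glyol
Ac	acyl_cap	C2H2O	42.010565		Ac
Oc	acyl_cap	C8H14O	126.104465		Oc
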