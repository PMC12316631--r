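name	sequence	organism	citation
Strigaibol A	Ac-Aib-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Vxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol B	Ac-Aib-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol C	Ac-Aib-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol D	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Vxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol E	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol F	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Vxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol G	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ala-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Strigaibol H	Ac-Aib-Aib-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma strigosum	strigaibols
Trikoningin KA V	Ac-Aib-Gly-Ala-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Lxxol	Trichoderma koningii	trikoningins
Tricholongin LBI	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol	Trichoderma cf. strigosum	tricholongins
Tricholongin LBII	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	Trichoderma cf. strigosum	tricholongins
Tricholongin LBIV	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	Trichoderma cf. pubescens	tricholongins
Trichostrigocin TSG-A	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	Trichoderma strigosum	trichostrigocins
Trichostrigocin TSG-B	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	Trichoderma cf. pubescens	trichostrigocins
Trichogin GB IX	Oc-Aib-Gly-Lxx-Aib-Gly-Gly-Lxx-Aib-Gly-Gly-Lxx-Aib-Gly-Lxx-Lxxol	Trichoderma longibrachiatum	trichogins
Lipostrigocin LSG A3	Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol	Trichoderma strigosum	lipostrigocins
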