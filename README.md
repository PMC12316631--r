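# peptaibr

Peptaibiomics in R: mass calculus, fragment-ion ladders, de novo sequence
assembly, novelty annotation and relative quantification for peptaibols and
lipopeptaibols.

## The problem

Peptaibols are linear fungal peptides (5–20 residues) built by nonribosomal
peptide synthetases (NRPS). They are rich in α-aminoisobutyric acid (Aib),
carry an N-terminal acyl cap (acetyl for peptaibols, a fatty acyl such as
octanoyl for lipopeptaibols) and end in a C-terminal β-amino alcohol instead
of a free acid. None of the standard proteomics stacks handle this
chemistry: the residues are nonproteinogenic, several of them are isobaric
(Leu/Ile, written `Lxx`; Val/Iva, written `Vxx`), and identification relies
on conventions of its own — notably the diagnostic in-source cleavage of the
central Aib–Pro bond, which splits a long peptaibol into a characteristic
b/y ion pair before MS² even starts.

`peptaibr` implements that workflow end to end for people who characterise
*Trichoderma* (and related) secondary metabolomes by LC–MS/MS:

* **chemistry** — a monoisotopic mass calculus over an extensible residue
  library. For a sequence with acyl cap `cap`, internal residues `r_1…r_n`
  and amino alcohol `alc`, the neutral mass is
  `M = Δ(cap) + Σ m(r_i) + m_free(alc)` (cap stored as the neutral
  substitution delta, alcohol as the free molecule; the terminal hydrogens
  cancel), with adducts `[M+H]+`, `[M+Na]+`, `[M+2H]2+`, `[M+2Na]2+`,
  `[M+H+Na]2+`.
* **fragmentation** — full singly charged b/y ladders
  (`b_k = Δ(cap) + Σ_{i≤k} m(r_i) + m_p`,
  `y_k = m_free(alc) + Σ_{i>n−k+1} m(r_i) + m_p`), the diagnostic Aib–Pro
  pair, water-loss ions, and the compound-table precursor convention
  (`b + y`, one proton above the true `[M+H]+`).
* **assembly** — de novo reading of observed ladders: longest-chain search
  over the peak graph, residue matching within `max(tol_ppm, abs_tol_da)`,
  terminal assignment, and integer-Da reporting of unexplained residual
  masses; plus repeat-unit detection and positional-isomer grouping.
* **annotate** — minimal-substitution comparison against a reference
  sequence database with the field's bracket notation
  (`[Aib]^1 → [Vxx]^1`), NRPS module-skip gap alignment for shortened
  variants, and Roman-numeral naming in elution order.
* **quantify** — peptaibiome composition from EIC peak areas (per-class and
  whole-peptaibiome percentages), count-based family consensus sequences and
  consensus-vs-most-produced comparison.
* **synthetic_data** — a seeded generator of ground-truthed peptaibiomes
  and MS² spectra (ppm-scale Gaussian mass error, decoy peaks, rank-decay
  intensities) so the whole pipeline is testable without instrument data.

The package ships curated compound tables of SF1 peptaibols and
lipopeptaibols from *Trichoderma* clade *Viride* strains and a small
reference peptaibiotics database as plain TSV under `inst/extdata/`.

## Worked example

```r
library(peptaibr)

p <- parse_peptaibol(
  "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol",
  label = "Strigaibol-like XII", rt = 29.66)

diagnostic_pair(p)
#>   series index bond        mz loss
#> 1      b    12   12 1180.6936 none
#> 2      y     7   12  740.4665 none

reported_precursor(p)   # the compound-table convention: b + y
#> [1] 1921.16
mh_plus(p)              # the true protonated molecular ion
#> [1] 1920.153

db <- read_reference_db(peptaibr_example("reference_peptaibiotics.tsv"))
nr <- nearest_reference(p, db)
nr$status; nr$distance
#> [1] "new"
#> [1] 1
substitution_notation(nr$matches[[2]]$substitutions)  # Strigaibol C
#> [1] "[Aib]^1 → [Vxx]^1"
```

The diagnostic pair (1180.69 / 740.47) identifies the compound in the
extracted-ion chromatogram; the b+y sum is what compound tables print as
the precursor; and the annotation says the sequence is one substitution
away from Strigaibol C — a new natural variant, named after its closest
known relative.

The numbered scripts under `analysis/` run the full workflow on the
packaged tables and write their outputs to `results/`:
`01_fragment_calculus.R` (recompute every printed b/y/[M+H]+ from the
sequences), `02_annotation.R` (novelty calls and module-skip placements),
`03_quantification.R` (per-strain shares, consensus vs most-produced),
`04_synthetic_benchmark.R` (residue-recovery grid of the de novo assembly
on simulated spectra).

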