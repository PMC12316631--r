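---
title: "Methods: peptaibol mass calculus, ladder assembly and peptaibiome analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptaibol mass calculus, ladder assembly and peptaibiome analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptaibr)
```

This vignette explains the models and conventions behind `peptaibr`, the
choices made where the design was genuinely open, and what the tests do and
do not establish.

## The molecules and the mass model

A peptaibol is modelled as an acyl cap, an ordered list of internal
residues (optionally interrupted by gap markers for skipped NRPS modules),
and a C-terminal amino alcohol — or, when MS² could not resolve the C
terminus, an unresolved residual mass. All masses are monoisotopic and
computed at full double precision; display rounds to 2 decimals, matching
how compound tables are printed.

The bookkeeping convention is the load-bearing choice. Internal residues
are stored as residue masses (amino acid − H₂O), the acyl cap as the
neutral substitution delta replacing one amine hydrogen (acetyl
+42.010565, octanoyl +126.104465), and the amino alcohol as its free
molecule. Under this convention the two terminal hydrogens cancel and the
neutral mass is a plain sum:

$$M = \Delta(\text{cap}) + \sum_i m(r_i) + m_\text{free}(\text{alcohol}).$$

This reproduces the printed `[M+H]+` of every internally consistent
lipopeptaibol row in the packaged tables to ≤ 0.012 Da (checked in
`analysis/01_fragment_calculus.R`).

Isobaric residues are never over-resolved: Leu/Ile collapse to `Lxx`,
Val/Iva to `Vxx` (likewise the corresponding alcohols). Gln vs Glu differ
by 0.984 Da and Gln vs Lys by 0.036 Da — both resolvable at Orbitrap-class
accuracy, which is why Gln/Glu calls are made but Leu/Ile never are. Lys
does not occur in peptaibols and is deliberately absent from the residue
library. The library is a packaged TSV; users can append tokens from a TSV
or YAML config without code changes.

## Fragment ions and the precursor convention

b ions accumulate from the cap, y ions from the alcohol, both singly
protonated; one ion per peptide bond. Two table conventions are modelled
explicitly rather than silently corrected:

* The precursor column of SF1 compound tables is numerically the **sum of
  the diagnostic b and y ions**, which carries two protons and therefore
  sits exactly one proton above the true `[M+H]+`. The package exposes
  both: `reported_precursor()` (b+y) and `mh_plus()` (true).
* Such tables label the N-terminal diagnostic fragment of a 19-residue
  compound "b13" although the cleavage N-terminal of Pro13 yields a
  12-residue b fragment. `peptaibr` indexes fragments by residue count;
  the printed label is display metadata only.

The diagnostic in-source cleavage requires exactly one Pro among the
internal residues; no Pro raises an explicit error (the caller falls back
to whole-molecule MS², the lipopeptaibol route) and multiple Pro is
reported as ambiguous. Only +1 fragments are modelled, and only b/y with
optional water loss: collision spectra of these compounds are interpreted
in that vocabulary, and a-ions or internal ions would add noise the
downstream logic never consumes.

## De novo ladder assembly

`infer_from_ladder()` reads an observed ladder by differencing: peaks are
nodes, and an edge connects two peaks whose mass difference matches an
internal-residue mass within `max(tol_ppm × mz, abs_tol_da)`. The default
tolerance is 5 ppm / 0.005 Da, appropriate for resolution-70,000 data. The
chain is found by exact longest-path dynamic programming over this DAG
(peptaibol ladders are far too small to need heuristics); ties are broken
by smaller cumulative |ppm| error, then lower starting m/z, and at equal
explanation score the solution using more peaks ranks first — a composite
step (e.g. Ala+Gly, which is exactly isobaric with Gln) must never displace
the two single-residue steps it shortcuts.

Terminal assignment anchors the chain: for a y ladder the lowest peak is
matched to alcohol + proton and the gap between the highest peak and the
precursor to the cap (optionally cap + one unread residue); for a b ladder
the roles swap. Mass that no residue/terminus combination explains becomes
`unexplained_residual`, stored at full precision and displayed at integer
Da — the convention used when C-terminally unresolved compounds are printed
as "…Gln + 146". The explanation score is the fraction of bonds explained,
with each unexplained residual counted as `max(1, round(residual / 110))`
missing residues (110 Da ≈ a typical residue mass).

When fragments overlap, no published rule says how competing ladder
interpretations were ranked; the ranking above is this package's own
choice and is recorded as such.

## Annotation, substitutions and module skipping

Novelty is assessed by position-wise comparison against equal-length
references only (the amino-alcohol terminus counts as a position — family
tables write substitutions like `[Lxxol]^19 → [Vxxol]^19`). All co-minimal
references are returned, displayed alphabetically, in the bracket notation
`[REF]^i → [OBS]^i`. Where a pair of equal-length sequences has identical
token multisets the package additionally flags a compositional (swap)
isomer, which is lossless and machine-checkable where a two-headed arrow in
a table is not. Note that reference databases can legitimately contain
distinct entries with identical token strings (true positional isomers
differing only in Leu/Ile/Val/Iva stereochemistry — e.g. Strigaibols B and
C); co-minimal reporting is therefore not an edge case but the normal
situation.

Length deficits of 1–3 residues are handled by `skip_alignment()`, which
enumerates every placement of the deficit as gaps in the template
coordinate system (≤ 3 gaps over ≤ 18 positions, i.e. at most 816
placements — exhaustive search is exact and instant) and keeps the
substitution-minimal placements. Among co-minimal placements the canonical
solution is the one a left-to-right scan produces: match the template as
long as possible, gap at the first mismatch. Formally: prefer substitution
positions as C-terminal as possible, then the rightmost gap vector. In a
run of identical template residues (Aib–Aib–Aib) this annotates the skip at
the *last* position of the run, which is how skipped modules are
conventionally numbered; the same rule places the two C-terminal gaps of a
triple-skip variant before, not after, the residue they precede. All
co-minimal placements remain available to the caller.

## Quantification and consensus

Relative quantification consumes extracted-ion-chromatogram areas
(integration is upstream): peptaibols are quantified under their major y
ion, lipopeptaibols under `[M+H]+`. Percentages are computed per strain at
full precision — per-compound share of class, share of the whole
peptaibiome, and class shares — and sum to 100 exactly before display
rounding (half-up, 2 dp). Published tables of this kind sometimes print
rows whose rounded shares sum to 99.5–100.7; the package reports exact-sum
values and makes no attempt to reproduce rounding anomalies.

The consensus of a family is computed per position over cap, residues
(gaps count as a token of their own, so skip variants do not shift the
coordinate system) and terminus. Two modes exist, and the default was
chosen empirically: the published family-consensus construction ("the most
abundant amino acid present at each position") is a **count** over
sequences, not an area-weighted vote — with area weighting the single
dominant compound sets every position and the documented
consensus-vs-most-produced differences (consensus Gln17 where the top
producer has Glu17; Lxx14 where the top producer has Vxx14) vanish.
`consensus_sequence()` therefore defaults to unweighted when no weights are
given, and `consensus_vs_top()` always compares the count-based consensus
against the largest-area compound. Area-weighted mode remains available
for production-centric questions. Ties are broken alphabetically and
flagged.

## The synthetic-data generator

`simulate_compounds()` draws sequences from family templates whose
position-specific alphabets encode the observed microheterogeneity
structure: the shipped SF1 template fixes the conserved
Gln6–Aib7–Aib8–Aib9–Ser10–Lxx11–Aib12–Pro13–Vxx14 core with probability 1,
varies the flanking positions over the residues seen in co-produced
variants, and allows module skips at positions 9, 16 and 17 with a default
per-compound probability of 0.05 (skipped variants are observed but rare —
well under a tenth of family members). Lipopeptaibol templates build the
7/11/15-residue octanoyl families on the repetitive Vxx/Lxx–Aib–Gly motif.
Abundances are log-normal with σ(log) = 1.5, reflecting compound tables in
which one family member can carry half the production while most sit below
1%; retention times are uniform over a 20–45 min window.

`simulate_spectrum()` emits the theoretical b/y peaks (for y including the
acyl-bond cleavage ion), perturbs each m/z with Gaussian error of σ ppm,
assigns rank-decay intensities (intensity ∝ rank^−e; intensities are used
only qualitatively downstream), and adds uniform decoy peaks either as a
Poisson density per 100 Da or as a fraction of the signal count. A single
seed drives everything; per-compound substreams are derived by counter so
outputs do not depend on generation order.

What the generator does **not** emulate: isotope envelopes, chromatographic
peak shapes, charge states above +1, chimeric spectra, intensity-dependent
mass error, and systematic (non-Gaussian) calibration drift. Passing the
simulation benchmarks therefore demonstrates the correctness of the
differencing logic under the stated noise model, not instrument-grade
performance on real data.

When benchmarking inference on spectra with σ ppm peak error, the matching
tolerance is scaled to 3·√2·σ (differencing two noisy peaks inflates the
step error by √2); with the default 5 ppm tolerance a 5 ppm-σ spectrum
would be rejected at almost every step.

## Problem sizes and numerical choices

The test suite and analysis scripts run at sizes chosen to exercise the
statistics without waste: the Monte-Carlo recovery benchmark uses 200
simulated 19-residue spectra at 5 ppm error with 20% decoys (mean residue
recovery ≈ 0.97); the substitution-rate calibration uses 4,000 draws
(binomial 99% band ± 0.012 around the 0.1 target); the half-normal
mass-error check pools ≈ 4,000 signal peaks. The packaged compound tables
are used whole (257 SF1 rows, 111 lipopeptaibol rows). Rows whose printed
masses are internally inconsistent with their own printed sequences (18 of
the SF1 rows, e.g. a printed b ion 0.12 Da off its own sequence) are
flagged `consistent = FALSE` at curation and excluded from exact-match
tests — they are reported, not reconciled, and no constant was tuned
toward them. One printed lipopeptaibol mass (669.48 vs 669.491 computed)
is likewise treated as a measured-value deviation.

## Known limitations

* Substitution distance is defined between equal-length sequences only;
  length differences go through gap alignment. Fuzzy matching across
  different terminal chemistry classes is out of scope.
* The ladder reader assumes one series per peak list; it does not
  deconvolve mixed b/y spectra or chimeric precursors, and it does not
  infer charge states from isotope spacing.
* Average masses, isotope-envelope prediction and elemental-formula
  inference from mass alone are non-goals.
* The shipped reference database is a small curated set for testing;
  real novelty assessment needs a comprehensive user-supplied database in
  the same TSV schema.
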