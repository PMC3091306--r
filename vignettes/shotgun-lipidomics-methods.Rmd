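---
title: "Methods: spectra alignment, fragmentation queries and isotopic correction in lipidscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra alignment, fragmentation queries and isotopic correction in lipidscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscan)
```

# The problem

Shotgun lipidomics infuses a total lipid extract directly into a tandem mass
spectrometer: no chromatography, so one acquisition is simply a set of MS1
survey scans plus data-dependent MS2 scans with a recorded precursor m/z.
Turning hundreds of such acquisitions into quantified lipid species requires
four things that this package implements:

1. **Scan averaging** -- repeated scans of one acquisition are merged into a
   representative spectrum by resolution-dependent mass binning;
2. **Cross-acquisition alignment** into a *MasterScan*, a flat-file database
   of precursor entries with per-acquisition intensity vectors and attached
   aligned MS2 fragment blocks;
3. **De novo identification** with a molecular fragmentation query language
   (MFQL) over sum compositions, compositional constraints and fragment
   patterns;
4. **Isotopic correction** of peaks whose isotope clusters partially overlap
   with neighboring species, in MS and MS/MS modes.

A synthetic-data module generates every dataset the validation needs, so the
whole package is testable without instrument files.

# Resolution-dependent binning

The central primitive is a left-to-right sweep over a mass-sorted peak list.
FWHM resolution is modeled as a linear function of mass,
`R(m) = R0 + gradient * (m - anchor)`; starting at the lowest unconsumed mass
`m`, all peaks in the half-open bin `[m, m + m/R(m))` are merged, and the
sweep resumes at the first peak beyond the bin. The bin width `m/R(m)` is the
FWHM of a peak at `m`, so a bin ideally centered on a Gaussian mass
distribution with the matching imprecision `sigma = m/(2R)` captures
`pnorm(1) - pnorm(-1) = 0.68` of the draws.

Two flavors of the same sweep are used:

* **Scan averaging** (within one acquisition): masses in a bin are averaged
  *weighted by intensity*; intuitively, strong peaks carry more reliable mass
  estimates. The normalization by the most intense member peak cancels
  algebraically, leaving the plain intensity-weighted mean.
* **Alignment** (across acquisitions): the representative mass is the plain
  *unweighted* mean of member masses, because spray conditions make
  intensities incomparable across acquisitions; every acquisition's member
  intensities are summed into its own slot of a per-bin intensity vector.

Because member masses are Gaussian around the true mass, a single pass splits
each true peak into roughly `2.7` bins (the sampled range spans about
`5.4 sigma` while a bin covers `2 sigma`). The sweep is therefore repeated;
each pass re-bins the current representative masses while representative
masses are always recomputed from the original member peaks. Three passes
suffice in practice -- afterwards no two adjacent representatives are closer
than `m/R(m)`, which the test suite asserts as an invariant. Far Gaussian
tails can leave sparse low-occupancy side bins beyond the merge reach of the
main bin; they are retained (they carry real observations) and are removed in
practice by the occupancy filter.

```{r template}
run_template_experiment(seed = 1)
```

This is the package's reimplementation of the classic template validation:
319 template masses spaced by `m/500` over 500--945 Da, 256 simulated spectra
with jitter `sigma = m/200000`, aligned at R = 100,000. One pass yields a
mean occupancy near 0.65 (the ideal 0.68 minus the anchoring loss: the first
bin of a cluster anchors at the lowest sampled mass, so the dominant bin
covers roughly `[-0.7 sigma, +1.3 sigma]`), three passes push it to ~0.97
with mean mass deviations well below 1 ppm.

## Noise filtering

Peaks below `min_sn` (default 3.0) times the estimated noise floor are
dropped per scan before binning. The noise floor is estimated as the median
intensity of the lowest-intensity half of the scan's peaks. If the implied
threshold would remove even the base peak, the estimate is deemed unusable
(uniform-intensity synthetic spectra have no noise population) and the filter
is skipped for that scan. Real instruments report signal-to-noise directly;
the estimator is only a stand-in for files that do not carry it.

# The MasterScan

Aligned precursor entries (mass, occupancy, per-acquisition intensity
vector) are associated with MS2 blocks by the recorded precursor m/z: a block
attaches to *every* precursor entry within half the isolation width (default
1.0 Da), since the instrument cannot have isolated more narrowly -- several
neighboring precursors legitimately share one MS2 spectrum. Blocks matching
no entry land in an `orphans` bucket.

Optional processing at import time:

* **Recalibration** against reference (lock) masses: the observed mass shift
  is fitted as a linear function of mass (a constant with a single
  reference) and subtracted. Fragment masses are only recalibrated when
  MS2-level references are supplied.
* **Pre-filters**: intensities below per-level thresholds are zeroed first,
  then occupancy (fraction of acquisitions with non-zero intensity, optionally
  within a named group) is recomputed and entries below `min_occupancy`
  are dropped. The replicate-majority rule common in benchmarking -- discard
  species seen in fewer than half the replicates -- is `min_occupancy = 0.5`.

Persistence is a versioned JSON flat file with full-precision numbers: saving
is deterministic (byte-identical re-saves) and loading reproduces the object
exactly. JSON was chosen over language-native serialization so the format is
documented, diffable and readable from any language.

# MFQL

A query names the fragments and precursors of a lipid class and how they
combine. `DEFINE` binds variables to explicit sum compositions
(`'C5 H15 O4 N1 P1' WITH CHG = +1`), bracket-range constraints
(`'C[30..48] H[30..200] N[1] O[8] P[1]'` with a charge and a DBR interval) or
plain masses. `IDENTIFY` places variables in `MS1+/-` or `MS2+/-` spectra,
combined with `AND`/`OR` (an `AND`-ed MS2 variable is only searched within
the MS2 blocks of matched precursors). `SUCHTHAT` is an arbitrary boolean
expression over peak attributes; `REPORT` defines the output columns,
including printf-style formatting with the two-string convention
`"PC [%d:%d]" % "(expr, expr)"`.

The implemented grammar (EBNF, reconstructed normative dialect of this
package):

```
query     := "QUERYNAME" "=" IDENT ";" define+ identify suchthat? report
define    := "DEFINE"? IDENT "=" (STRING | NUMBER) with? ";"
with      := "WITH" witharg ("," witharg)*
witharg   := "CHG" "=" SIGN? NUMBER | "DBR" "=" "(" NUMBER "," NUMBER ")"
identify  := "IDENTIFY" clause (("AND"|"OR") clause)* ";"?
clause    := IDENT "IN" ("MS1"|"MS2") ("+"|"-")
suchthat  := "SUCHTHAT" expr ";"
report    := "REPORT" (IDENT "=" expr ";")+
expr      := or; or := and ("OR" and)*; and := not ("AND" not)*
not       := "NOT" not | cmp
cmp       := add (("<"|">"|"<="|">="|"=="|"!=") add)?
add       := mul (("+"|"-") mul)*; mul := unary (("*"|"/"|"%") unary)*
unary     := "-" unary | postfix
postfix   := primary ("." IDENT | "[" (IDENT|NUMBER) "]")*
primary   := NUMBER | STRING | IDENT ("(" expr ("," expr)* ")")? | "(" expr ("," expr)* ")"
```

Peak attributes: `.mass` (observed m/z), `.chemsc` (bound composition;
`[C]` indexes an element count, `[db]` the double-bond equivalent),
`.errppm`/`.errda` (observed minus theoretical), `.intensity` (the
per-acquisition vector), `.occupation`. Builtins: `isEven`, `isOdd`, `abs`.
`%d` truncates toward zero; a bare `%f` prints one decimal. The format
operator's right-hand string is re-parsed as an expression tuple.

Evaluation binds constraint-defined MS1 variables by exhaustive composition
enumeration within the MS1 tolerance (default 5 ppm) -- a depth-first search
over the element ranges with running mass bounds, verified against a
brute-force oracle. If several compositions match one precursor, each yields
its own report row flagged `AMBIGUOUS` rather than being silently merged. MS2
variables match within the entry's fragment block at the MS2 tolerance
(default 0.3 Da, an ion-trap setting; pass ppm for high-resolution MS2).
Neutral losses are expressed arithmetically in `SUCHTHAT`
(`prec.mass - frag.mass`), not with a dedicated keyword, since the section
already supports full arithmetic.

## Double-bond equivalents

DBR uses the generalized valence form `1 + sum n_i (v_i - 2) / 2`, i.e.
`1 + C - H/2 + (N + P)/2` with trivalent phosphorus, evaluated on the ion
formula exactly as written. Protonated even-electron cations therefore have
half-integral DBR: protonated PC 36:1 (`C44 H87 N1 O8 P1`, +1) gives 2.5 and
the query idiom `prPC.chemsc[db] - 1.5` its one genuine double bond. This is
the only convention under which the standard constraint `DBR = (1.5, 7.5)`
and the naming arithmetic are mutually consistent, which is why it was
chosen over neutralizing the formula first.

# Isotopic correction

At unit resolution the M+2 isotopologue of a lipid with one more double bond
falls onto the monoisotopic peak of its saturated-by-one neighbor 2 Da up
(the exact offset is ~9 mDa, unresolvable below R ~ 40,000 at m/z 700). An
isotopologue is deemed to contribute to a peak when their distance is below
`m/(2R(m))`, so the same code reproduces both the unit-resolution merge and
its disappearance at R = 100,000.

**MS mode** (`correct_ms`): identified species are swept light to heavy;
each species' expected M+1..M+depth intensities (its natural isotope
pattern, computed by per-element polynomial convolution aggregated by
nominal mass offset, times its *current corrected* monoisotopic intensity)
are subtracted from any identified peak within the overlap window. Corrected
intensities feed the cascade, so chains of overlapping clusters unwind; the
sweep is independent of input order, never subtracts more than
`I0 * (M+k/M0)`, floors at zero and records every subtraction (and clip) in
an auditable ledger.

**MS/MS mode** (`correct_msms`): the contamination is indirect. A heavier
species' isolation window co-isolates the M+k isotopologues of lighter
precursors; their fragments carry 0..k of the heavy isotopes, distributed
hypergeometrically over the carbon skeleton (carbon dominates lipid
envelopes, so the transfer uses carbon counts only). The sweep subtracts,
from every block whose window contains an isotopologue of a lighter
identified precursor, the expected fragment isotopologue intensities:
corrected own-block fragment intensity x precursor isotopologue abundance x
transfer probability. With a narrow window and `k = 0` only, nothing is
subtracted -- a monoisotopic-only setting (correction depth 0) is the
identity.

The PA-standards experiment wires it together:

```{r pa}
r <- run_pa_experiment(seed = 42)
round(r$ms_ratio, 3)        # corrected MS precursor ratios, expected 10:1:1
round(r$ms_ratio_raw, 3)    # uncorrected: the middle species is overestimated
round(r$msms_ratio, 3)      # corrected acyl-anion sums, expected 1:9:1:1
```

# The synthetic-data generators

`make_template()`/`generate_template_spectra()` implement the alignment
validation (analytic template, Gaussian jitter, unit intensities).
`lipid_ground_truth()` + `simulate_acquisitions()` build full MS1/MS2
datasets: isotope envelopes from the same pattern code, per-acquisition and
per-peak multiplicative log-normal intensity noise (default cv 10%, kept
log-normal so intensities stay positive), Gaussian mass jitter
`sigma = m/(2 R_jitter)` at each MS level, data-dependent MS2 spectra per
distinct monoisotopic precursor with co-isolation of every isotopologue
inside the window, and optional uniform chemical noise peaks for stressing
the S/N filter.

Deliberate simplifications -- what passing tests do and do not show:

* centroids only, no peak shapes or detector saturation;
* jitter resolution is a generator parameter separate from the analysis
  resolution model (an ion trap's centroid scatter is better than its FWHM
  resolution; the PA simulation uses jitter R = 10,000 while binning and
  correcting at R = 800);
* the isotopologue-to-fragment transfer in the simulator and the corrector
  share the carbon-only hypergeometric model, so the PA recovery test
  validates the bookkeeping and the sweep order, not that model itself;
* intensity noise is independent across peaks; real spray fluctuations
  correlate within a scan.

Problem sizes used in the shipped validation: 256 spectra x 319 peaks x 5
seeds for the alignment statistics; 4 acquisitions x 3 scans for the PA
mixture; 5 PE species x 3 acquisitions for the ether-lipid misassignment
survey. These match the published experiment scales where stated and keep a
full validation run in the tens of seconds.

# Numerical and design choices

* Electron mass is subtracted/added per charge in all m/z arithmetic;
  required at sub-ppm accuracy.
* The isotope table (IUPAC masses, representative abundances) is embedded in
  the package for offline reproducibility.
* Enumeration output is sorted by absolute mass error, ties broken by the
  formula string; binning sweeps are deterministic on sorted input, equal
  masses merging in input order -- reruns are byte-identical end to end.
* Bins are half-open and anchored at the lowest unconsumed mass; this
  one-sided convention is what produces the 0.65 (rather than the ideal
  centered 0.68) one-pass occupancy.
* Same-acquisition peaks landing in one alignment bin are summed, so each
  acquisition owns exactly one vector slot per entry.
* Degenerate inputs: empty compositions, negative counts from composition
  subtraction, mixed-polarity alignment, unsorted peak lists and zero-width
  bins all raise immediately rather than propagating.

# Limitations

* No MS3, no profile-mode centroiding, no vendor raw formats (mzXML and
  two-column peak lists only), no cross-polarity merging, no incremental
  MasterScan updates (rebuild instead).
* Ion abundances are reported as-is; conversion to molar concentrations is
  out of scope.
* The MFQL dialect is this package's documented reconstruction; precedence
  and builtins are as specified above.
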