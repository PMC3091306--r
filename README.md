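# lipidscan

Informatics for direct-infusion ("shotgun") lipidomics on tandem mass
spectrometers: resolution-dependent scan averaging, cross-acquisition
alignment of MS/MS datasets into a flat-file **MasterScan** database, a
**molecular fragmentation query language (MFQL)** for de novo lipid
identification and quantification, exhaustive sum-composition enumeration
under elemental constraints, and **isotopic correction** of partially
overlapping isotope clusters in both MS and MS/MS modes.

The intended users are lipidomics and metabolomics groups processing large
series of direct-infusion acquisitions (technical/biological replicates,
blanks, controls) who want instrument-independent, scriptable processing of
mzXML or plain peak-list data -- and method developers who need a fully
synthetic, ground-truth-controlled test bed for alignment and isotope
arithmetic.

## The algorithms in brief

**Binning.** FWHM resolution is modeled linearly, `R(m) = R0 + g (m - a)`.
A mass-sorted peak list is swept left to right; all peaks in the half-open
bin `[m, m + m/R(m))` merge into one. Within an acquisition, bin masses are
intensity-weighted means,

    m_avg = sum(I(m_i) m_i) / sum(I(m_i)),   m_i in bin B,

and across acquisitions they are unweighted means with one intensity-vector
slot per acquisition. The sweep is repeated (three passes by default) until
no two adjacent representatives are closer than `m/R(m)`.

**MFQL.** A query defines fragments and precursors as sum compositions
(`'C5 H15 O4 N1 P1' WITH CHG = +1`) or constraints
(`'C[30..48] H[30..200] N[1] O[8] P[1]' WITH CHG = +1, DBR = (1.5, 7.5)`),
places them in MS1/MS2 spectra with AND/OR, filters binding sets with
arbitrary arithmetic (`SUCHTHAT isEven(prPC.chemsc[C])`), and formats report
rows. Double-bond equivalents use `1 + C - H/2 + (N + P)/2` on the ion
formula as written. Constraint matching is exhaustive enumeration within a
ppm tolerance, checked against a brute-force oracle in the tests.

**Isotopic correction.** Expected isotopologue intensities are computed from
the identified compositions (per-element polynomial convolution) and
subtracted light-to-heavy wherever the resolution window `m/(2R)` cannot
separate them; in MS/MS mode the subtraction follows the co-isolated
precursor isotopologues, with heavy isotopes distributed hypergeometrically
over the fragments' carbon skeletons.

## Worked example

The classic template validation -- 319 peaks spaced `m/500` over 500-945 Da,
256 simulated spectra with Gaussian mass jitter `sigma = m/200000`, aligned
at R = 100,000:

```r
library(lipidscan)
run_template_experiment(seed = 1)
#>   passes n_entries mean_occupancy mean_abs_mda mean_abs_ppm
#> 1      1      1026          0.643        0.871         1.25
#> 2      2       649          0.873        0.829         1.19
#> 3      3       455          0.974        0.322         0.46
```

One binning pass recovers each template mass with a mean occupancy of ~0.65
(a resolution-wide bin captures 68% of Gaussian draws, minus the anchoring
loss) and a mean mass deviation below 1 mDa; after three passes occupancy is
~0.97 and the deviation ~0.4 ppm.

The four-standard phosphatidic-acid mixture (molar 1:9:1:1, two standards
exactly isobaric) at unit resolution, quantified before and after isotopic
correction:

```r
r <- run_pa_experiment(seed = 42)
round(r$ms_ratio, 2)       # corrected MS precursor ratios
#> [1] 10.06  0.99  1.01    # expected 10 : 1 : 1
round(r$ms_ratio_raw, 2)   # uncorrected: PA 18:0/18:1 overestimated
#> [1] 6.30 1.30 0.70
round(r$msms_ratio, 2)     # corrected acyl-anion sums per species
#> [1] 1.00 8.98 0.98 0.96  # expected 1 : 9 : 1 : 1
```

Identifying phosphatidylcholines with the shipped query
(`inst/extdata/phosphatidylcholine.mfql`) against a synthetic positive-mode
MasterScan reports the species name built from composition arithmetic:

```r
q <- read_mfql(system.file("extdata", "phosphatidylcholine.mfql",
                           package = "lipidscan"))
rep <- evaluate(q, ms, tol_ms1 = tol_ppm(5), tol_ms2 = tol_da(0.01))
rep[, c("NAME", "CHEMSC", "ERROR")]
#>        NAME           CHEMSC ERROR
#> 1 PC [36:1] C44 H87 N1 O8 P1  0ppm
```

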