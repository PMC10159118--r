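---
title: "Methods: GC-content bias in amino-acid and secondary-structure composition"
author: "gc2struct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-content bias in amino-acid and secondary-structure composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gc2struct)
```

## The scientific question

Prokaryotic genomes span a remarkably wide range of genomic GC content
(roughly 20% to 75% in coding regions). Because the 61 sense codons differ
in their G+C count, GC-rich genomes are pushed toward amino acids encoded
by GC-rich codons (Ala, Gly, Pro, Arg, Trp) and away from those with
AT-rich codons (Lys, Asn, Ile, Phe, Tyr, ...). Since the 20 amino acids
also differ in their propensity to sit in alpha-helices, beta-strands and
random coil, a compositional shift at the DNA level can propagate all the
way to the secondary-structure composition of whole proteomes, and even to
the Chou-Fasman conformational parameters, which are classically treated
as universal constants of protein chemistry.

`gc2struct` implements this analysis chain as a reusable, tested pipeline:
coding-region GC content, proteome amino-acid composition, per-structure
composition, conformational parameters, GC-trend regression, and an
orthologous-group (COG) analysis that asks whether individual protein
families show structure composition drifting with the GC of their genes.

## Estimators

All quantities are pooled ("residue-weighted") over a proteome.

* **Coding GC.** `compute_coding_gc()` returns
  \(\mathrm{GC}_G = \sum_g \mathrm{GC}(g) / \sum_g |g|\) over the coding
  genes \(g\) of genome \(G\). Ambiguous bases (`N`) are excluded from
  numerator and denominator. Stop codons are part of the CDS as given and
  therefore counted; their contribution is below 1% of gene length.

* **Codon-GC classes.** `classify_amino_acids()` computes, for each amino
  acid, the unweighted mean over its synonymous codons of (G+C)/3, and
  classes it as `high` (> 1/2), `neutral` (exactly 1/2, tolerance 1e-9) or
  `low`. The mean is unweighted (a property of the code, not of usage);
  all standard-code means are exact multiples of 1/12 or 1/18, so the
  boundary is crisp and the partition is always 5/8/7.

* **Amino-acid frequencies.** `aa_frequencies()` returns
  \(\mathrm{aa}_G = \sum_p |p(\mathrm{aa})| / |P(G)|\); `X` residues are
  excluded everywhere, which keeps every frequency table summing to
  exactly 1. `aa_frequencies_by_ss()` restricts the counts to residues
  annotated `H`, `E` or `C`.

* **Conformational parameters.** With \(|ss(p,\mathrm{aa})|\) the number
  of residues of type `aa` in state `ss` of protein `p`,
  \[
    F_{ss}^{aa} = \frac{\sum_p |ss(p,\mathrm{aa})|}{\sum_p |p(\mathrm{aa})|},
    \qquad
    F_{ss} = \frac{\sum_p |ss(p)|}{|P(G)|},
    \qquad
    \mathrm{CP} = F_{ss}^{aa} / F_{ss}.
  \]
  `conformational_params()` returns all three plus raw counts. Two exact
  identities follow from the definitions and are enforced in the test
  suite: \(\sum_{ss} F_{ss}^{aa} = 1\) per amino acid, and the
  frequency-weighted mean CP equals 1 for every state. Amino acids absent
  from a proteome are reported as *missing* (with their zero counts), never
  as CP 0: "absent" and "never in helix" are different facts. Although CP
  values are often described as ranging from 0 to 2, the ratio is not
  mathematically capped and the package imposes no ceiling.

* **Structure composition.** `ss_composition()` returns helix/sheet/coil
  fractions pooled over a proteome or per protein
  (\(|ss(p)|/|p|\)); the pooled value equals the length-weighted mean of
  the per-protein values.

* **CP categories.** `categorize_cp()` maps CP to the five classical
  labels (strong breaker ... strong former) by four cut points. The
  defaults (0.6, 0.9, 1.1, 1.4) are this package's convention - the
  categorisation is a presentation layer on top of the numeric CP
  pipeline, and any published threshold set can be passed instead.

## Secondary-structure annotations

The pipeline consumes per-residue three-state annotations as a FASTA-like
file over `{H, E, C}` with the same IDs and lengths as the protein FASTA;
they may come from any predictor or from DSSP-style assignments reduced to
three states. The reduction convention on import is: `H` and `E` are kept,
every other character becomes `C`, and the number of remapped characters
is reported. Proteins lacking an annotation stay in the compositional
statistics but are excluded from all structure statistics.

## Regression and significance reporting

`fit_gc_trend()` is ordinary least squares of a response on GC (fraction
scale), degree 1 or 2; the reported p-value is the two-sided t-test on the
slope (degree 1) or the quadratic coefficient (degree 2). `"auto"` keeps
the quadratic only when the nested F-test rejects at 0.05 - some
responses (amino acids such as Met or Gln) are visibly curved in GC.
Significance codes follow the conventional star scheme with right-closed
intervals: `p <= 0.001` is `'***'`, then `'**'`, `'*'`, `'.'`, `' '` at
0.01/0.05/0.1. A zero-variance response is flagged and reported as slope
0 with p 1 rather than as a failed fit. No multiple-testing correction is
applied across the 20 x 3 regression family; raw p-values are reported,
and users may correct downstream with `p.adjust` if desired. In output
tables slopes are reported per GC *percent* (internal slope / 100), the
scale on which such trends are conventionally quoted.

`call_cog_bias()` fits the three per-state regressions for one COG against
the members' gene GC and calls the family *biased* when at least two of
the three slope p-values fall below 0.001. Two-of-three at 0.001 is a
stringent joint criterion: under the null the family-wise rate is about
\(3 \times 0.001^2\), and the test suite verifies a realised rate at or
below 0.005 over 1000 null families. Members are fitted unweighted;
duplicated sequences are not collapsed.

## COG representative selection

Orthologous families are filtered in a single pass with both statistics
taken from the unfiltered group: (1) member length within one sample
(n-1) standard deviation of the group mean - removing multidomain
outliers; (2) conserved-domain span (1-based inclusive,
`end - start + 1`) at least 80% of the group's mean domain length -
removing partial domains. Both boundaries are inclusive ("no more than",
"at least"). The filter is deliberately not iterated; re-applying it with
frozen statistics is a no-op, which the tests assert.

## Secondary-structure alignment

`align_ss()` aligns the H/E/C strings of a family directly (rather than
aligning amino-acid sequences and projecting): pairwise global
Needleman-Wunsch scores with affine gaps (Gotoh) feed an average-linkage
guide tree (base R `hclust`), and profiles are merged bottom-up with the
same dynamic programme. The scoring convention is: match +2, H/E confusion
-2, any mismatch against C -1, gap open -4 (covering the first gap
position), gap extension -1; profile columns score as the expected
substitution score over the two column state distributions, with gap
proportions contributing 0. Traceback prefers match, then a gap in the
second profile, then the first, making the output deterministic given the
input order. Pairwise scores are verified against exhaustive enumeration
of all alignments for short strings, and every alignment row reproduces
its input exactly after gap removal. Externally produced alignments can be
imported via `read_ss_alignment()` for exact reproduction of results
obtained with a general-purpose aligner.

## The synthetic genome generator

`generate_genome()` exists so that every downstream stage has a ground
truth. Design:

* **Codon sampling.** Body codons are drawn from the 61 sense codons with
  weight \(w(c) \propto \exp(\lambda\, \mathrm{gc}(c))\). A single tilt
  parameter makes the target GC a one-dimensional root-finding problem,
  solved by bisection to 1e-4. Because each gene also carries a fixed
  `ATG` start and a stop codon drawn with the same tilt, the bisection
  targets the expected GC of *whole genes* at the spec's mean length;
  ignoring the start/stop contribution would bias realised GC by about
  0.002 at extreme targets, which is material against the generator's own
  3-sigma targeting guarantee.
* **Gene lengths** are negative-binomial (mean and dispersion in the
  spec), floored at 50 codons so that short proteins do not destabilise
  per-protein composition statistics. Defaults (mean 300 codons,
  dispersion 10) give a realistic protein-length distribution.
* **Structure states** are drawn per residue from a 20 x 3 propensity
  matrix \(P(ss \mid aa)\); with probability `persistence` a residue
  copies its predecessor's state instead, creating realistic helix/strand
  runs. The default matrix follows the classical Chou-Fasman tendencies
  around a 0.35/0.25/0.40 helix/sheet/coil baseline.
  `gc_coupled_propensity()` additionally tilts the coil odds with the
  genome's GC, producing the qualitative pattern of interest (coil rising,
  helix and sheet falling with GC) with a known sign.
* **Ground truth.** With `persistence = 0` the implied conformational
  parameters have the closed form
  \(\mathrm{CP}(aa,ss) = P(ss \mid aa) / \sum_{aa'} f(aa') P(ss \mid aa')\)
  (`expected_cp()`), which the estimator must recover. The generator also
  records realised GC and per-protein composition bookkeeping.
* **Determinism.** One seeded RNG stream per call, saved and restored, so
  identical specs give byte-identical FASTA output and the generator never
  perturbs the caller's RNG.

What the generator does *not* emulate: phylogenetic correlation between
organisms, codon-usage structure beyond the GC tilt, amino-acid
composition/GC coupling beyond what codon tilting induces, and sequence-
context-dependent structure (with `persistence > 0` the marginal state
propensities are deliberately shrunk toward the proteome mean, which is
why the closed-form oracle is restricted to `persistence = 0`). Passing
tests therefore demonstrate correctness of the estimators and the
detection machinery, not biological realism of any particular genome.

## Problem sizes and numerical choices

The validation suite uses problem sizes chosen by power analysis, small
enough to run on one CPU in minutes:

* CP recovery uses one genome of 2,700 genes x 300 codons (~8e5
  residues). For the rarest amino acid at GC 0.5 (Trp, ~1.6% of
  residues), three binomial standard errors of the CP estimate are ~0.044
  at that size, inside the +/-0.05 acceptance band; at the 5e5-residue
  floor they would be ~0.055.
* GC targeting is checked at targets 0.25-0.70 with 300 x 300-codon
  genes against the 3-sigma binomial bound on the realised GC.
* The trend-sign recovery study uses 30 genomes (100 genes x 150 codons)
  across GC 0.25-0.70 with coil-GC coupling 2; per-genome composition
  noise (~0.004) is an order of magnitude below the induced effect.
* Type-I control of the COG bias caller uses 1,000 null families of 50
  members.

Numerical conventions: `neutral` codon class at exactly 1/2 with absolute
tolerance 1e-9; frequency tables sum to 1 within 1e-9; degenerate
regressions (constant response, perfect fit) are flagged rather than
propagating NaN; the aligner breaks ties deterministically as described
above; COG domain coordinates are 1-based inclusive everywhere.

## Known limitations

* Three-state reduction of richer structure alphabets is a convention
  (non-H/E to C), not a calibrated mapping.
* The COG bias criterion tests only *linear* trends in composition;
  nonlinear structure-GC relationships inside a family would be missed.
* The built-in SS aligner is a stand-in for general-purpose multiple
  aligners; its scoring scheme for the 3-letter alphabet is declared, not
  fitted, and `read_ss_alignment()` exists precisely so external
  alignments can be used for exact reproduction.
* Regressions treat organisms as independent; no phylogenetic correction
  (e.g. PGLS) is applied.
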