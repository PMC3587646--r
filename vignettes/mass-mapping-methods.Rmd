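---
title: "In-silico primary-structure characterization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico primary-structure characterization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massmapr)
library(dplyr)
```

massmapr implements the in-silico side of the standard orthogonal workflow
for confirming the primary structure of a glycosylated Fc-fusion protein —
the kind of homodimeric VEGF-trap receptor decoy produced in CHO cells for
anti-angiogenic therapy. The wet-lab side of that workflow (tryptic
digestion with and without reduction, PNGase F treatment, LC-MS on an ion
trap, 2-AA labeling of released glycans, capillary electrophoresis for pI)
produces peak lists; this package produces the theory those peaks are
matched against, performs the matching, and assembles the evidence into a
characterization report. This vignette explains each model, its
assumptions, the tunable parameters, and the limits of what the synthetic
fixtures can demonstrate.

## Mass model

All arithmetic is carried out on explicit mass scales. Monoisotopic
residue masses derive from standard IUPAC atomic masses; average masses
use conventional elemental weights. The constants that matter:

* water 18.010565 Da (mono), added once per free peptide;
* proton 1.007276 Da, converting neutral mass to MH+ and to m/z at any
  charge;
* H2 2.015650 Da (mono), lost once per disulfide bond;
* isotope spacing 1.003355 Da, the offset of a mis-picked +1 isotope peak.

Modifications are applied instances with explicit deltas: carbamidomethyl
(+57.02146 Da on Cys, the blocking-agent adduct of the reduced workflow,
fixed), deamidation (+0.98402 Da on Asn/Gln, variable — or the fixed
PNGase F signature at occupied sequons), oxidation (+15.99491 Da on Met,
variable). The test suite cross-checks every residue and monosaccharide
mass against an independent oracle that recomputes them from elemental
formulas and isotope masses, so the tables and the oracle cannot share a
transcription error.

Published ion-trap tables do not state whether their MH+ values are
monoisotopic or average — at unit resolution several values fall between
the two. The package therefore computes both scales everywhere and
matches at instrument tolerance rather than asserting a scale.

## Digestion

Trypsin is modeled as cleavage after K or R unless the next residue is P.
Zero-missed-cleavage peptides tile the chain exactly — contiguous,
non-overlapping, covering every residue — and every peptide with m missed
cleavages is the concatenation of m+1 adjacent tiles; both properties are
enforced by tests, as is mass conservation (the water-corrected peptide
mass sum equals the chain mass on both scales). No minimum peptide length
is imposed by default: real reference peptides run as short as six
residues, and length filters are an argument, not a policy.

The non-reduced digest reuses the same cleavage rule — disulfides do not
alter trypsin specificity — and instead retains each peptide's cysteine
positions in global chain coordinates so the linkage stage can reason
about them. Its missed-cleavage default is 1 (linked peptides often
retain a missed site), while the reduced peptide map defaults to 0.

## Matching

Peaks enter as MH+ or as (m/z, charge) and are canonicalized to neutral
monoisotopic mass. Each peak receives its best candidate within tolerance:
smallest absolute error, ties broken by fewer modifications, then
lexicographic sequence — a deterministic rule verified against a
brute-force all-pairs oracle on random instances. The default tolerance
is ±0.5 Da, the practical accuracy of a unit-resolution ion trap;
published deviations of reference peptides from theory reach ~0.25 Da.

Two known reference peptides only make sense ~1 Da above theory, the
signature of the instrument picking the +1 isotope peak of a weak
precursor. The matcher therefore optionally (and in the pipeline, by
default) retries unmatched peaks with a −1.003355 Da correction and flags
the result as an isotope-offset match rather than silently absorbing a
1 Da error into a wide tolerance.

PNGase F occupancy readout: the enzyme converts each occupied sequon Asn
to Asp, so in the treated sample every sequon-bearing peptide appears
+0.98402 Da per occupied site. `apply_pngasef()` applies exactly that to
the theory; a sequon is then *confirmed* occupied when a deamidated
peptide covering it is matched. In the untreated mode deamidation is
instead a variable modification, and `expand_variants()` enumerates all
placements up to a cap (each residue carries at most one modification).

Coverage is the union of matched peptide intervals over the chain. The
chains of a homodimer are indistinguishable in a peptide map, so matches
are credited to every sequence-identical chain before coverage is
computed.

## Disulfide mapping

The topology is a list of cysteine pairs in chain coordinates. Peptides
from the non-reduced digest are nodes; bonds are edges between the
peptides containing the bonded cysteines; every connected component with
at least one bond is a linked species with mass

$$M = \sum_i M_i - 2.01565\,b$$

for b bonds (each bond removes two hydrogens). The two symmetric hinge
peptides of the homodimer joined by the two inter-chain bonds form a
*single* homo-di-peptide species with b = 2 — one peak in a spectrum, so
one row in the species table — and species identical up to chain
relabeling are collapsed with their multiplicity recorded. On the preset
topology this accounting yields exactly five distinct di-peptide species.

Scrambling detection follows the exhaustive logic: enumerate *all*
hypothetical cysteine-linked di-peptides — every unordered pair of
distinct Cys-bearing peptide species including self-pairs, $\binom{k}{2}+k$
single-bond combinations for k species, plus double-bond variants where
both members carry two link points — and report any observed peak that
matches a hypothetical-but-not-expected mass, naming the offending pair.
Intra-peptide loops (both cysteines on one peptide, mass M − 2.01565) are
supported but absent from the preset topology.

## Glycan model

Compositions are stored exactly as the field writes them: antenna counts
of Hex, HexNAc, Deoxyhexose and NeuAc kept separate from the constant
(Man)3(GlcNAc)2 core flag, e.g.
`(Hex)2(HexNAc)2(Deoxyhexose)1(NeuAc)2 + (Man)3(GlcNAc)2`. Deoxyhexose
is fucose mass-wise; no linkage or isomer information is represented.
Free reducing glycans add one water; 2-AA labeling (reductive amination
with anthranilic acid, C7H7NO2) adds a constant
137.047679 − 18.010565 + 2.015650 = +121.052764 Da derived from atomic
composition. A glycopeptide is the peptide (sequon Asn *unmodified*) plus
the glycan residue mass — glycosidic attachment adds no water. This makes
the identity

(glycopeptide mass) − (deglycosylated deamidated peptide mass)
= (glycan residue mass) − 0.98402

hold for every site, tying the glycopeptide table to the PNGase F peptide
map; a test asserts it across the whole library.

Composition search enumerates the bounded lattice (defaults hex ≤ 10,
hexnac ≤ 8, deoxyhexose ≤ 3, neuac ≤ 4, core required) and returns every
composition within tolerance sorted by absolute error with deterministic
tie-breaks. Near-degeneracies are real at wide tolerance (e.g. compositions
differing by NeuAc versus Hex combinations); they are reported, not
resolved. Per-site assignment ranks matched glycoforms by intensity when
intensities are present and by error otherwise, keeping the top three by
default — the conventional "most abundant structures per site" table.
Whether a real instrument ranked by peak height or area is unknowable from
a printed table, so the ranking input is simply whatever intensity column
the peak list carries.

## Isoelectric point and the deglycosylation shift

Net charge at a given pH is the Henderson–Hasselbalch sum over N-terminus,
C-terminus, D, E, C, Y, H, K, R and any extra acidic groups, with the
Bjellqvist pKa set as default (overridable); sialic acid carboxyls
contribute as extra acids at pKa 2.6. The charge curve is strictly
decreasing, so the pI — its root on pH 0–14 — is unique and found by
bisection to |charge| < 1e−4. Monotonicity (more acids never raise the pI,
more bases never lower it) is property-tested.

Deglycosylation moves two quantities at once: each released site gains an
Asp (one acid, pKa 4.05) and loses its glycan's sialic acids (pKa 2.6).
Above pH ~5 both are nearly fully ionized, so the *direction* of the pI
shift is set by whether the average sialic load per site exceeds one. The
per-site top-3 glycoform tables of such proteins list disialylated
species first at several sites, which alone would predict a basic shift —
but a released-glycan chromatogram of CHO material shows a long tail
(20+ major peaks) of mostly neutral species beyond the top three. The
package therefore treats the listed glycoforms as a stated fraction of
each site's pool (`fraction_of_pool` in the fixture: 0.33/0.18/0.09 per
rank, 0.60 total; `glycan_pool_fraction = 0.6` in the pipeline's pI
summary), the remainder asialo. That yields a site-averaged load of
~0.63 NeuAc and the experimentally observed *acidic* shift. Users with
complete glycan quantification should set the pool fraction to 1 and
supply the full table.

The PNGase F time course models site release as first-order decay with a
default rate of 0.1 h⁻¹ — about half the sites released by 7 h and ~99%
by 48 h, matching the qualitative trajectory of snapshot experiments at
those times; true PNGase F kinetics on an intact protein are not
quantified anywhere we know of, so the rate is a stated, configurable
stand-in. Each site is independently released (Asp, no glycan) or
occupied with a glycoform drawn from its pool; the assembly's
charge-state distribution is the exact convolution of the per-site
distributions, and each (released, sialic) state gets a bisection pI.
The untreated profile is a heterogeneous multi-peak distribution (the
CE picture of a sialylated glycoprotein), the mean pI decreases strictly
with treatment time, and the profile collapses to the single fully
deamidated species at long times.

## Synthetic fixtures: what they do and do not show

The preset fixture (`make_fixture()`) generates a two-chain homodimer
with the architecture of a VEGF-receptor/Fc fusion: seven sequons, each
on its own tryptic peptide of 5–20 residues; a hinge-like peptide
carrying two adjacent cysteines (CPPCP motif) forming the two inter-chain
bonds; and intra-chain bonded pairs spanning two peptides in each of two
receptor-like domains and two pairs in the Fc-like region — ten bonds and
five distinct linked di-peptide species per assembly. Filler segments
exclude K/R (no stray cut sites), C (all link points designed), N (no
stray sequons), and never start with P (which would block the preceding
cleavage); everything is deterministic under the seed.

The sequence itself is *generated*: the real molecule's sequence is not
public, so the fixture reproduces the printed feature counts without
claiming sequence identity. Consequently, pipeline results that depend
only on architecture (sequon count, species accounting, coverage logic,
shift directions) are demonstrated by the fixture, while absolute
published values that depend on the real sequence — full-protein
coverage of the actual molecule, its pI range of 5.68–7.47, the identity
of the 20+ released-glycan peaks — are not reproducible here and are not
claimed. The four printed reference peptide masses are the exception:
their sequences are published, and the package reproduces their observed
MH+ values within ion-trap tolerance from the sequences alone.

The peak-list simulator emulates ion-trap observation: Gaussian mass
error (default σ = 0.2 Da, chosen to mirror the 0.1–0.3 Da deviations of
printed reference values), a +1 isotope mis-pick probability (default
0.1 — two of seven printed reference peptides show the ~+1 Da pattern),
dropout, and uniform contaminants over the m/z 500–2000 scan window. It
does not model isotope envelopes, retention time, or realistic intensity
distributions. Under these defaults, ≥95% of species are recovered at
±0.5 Da tolerance (20-replicate property test); noiseless simulation
round-trips the truth tables exactly.

## Numerical choices and degenerate inputs

* Bisection terminates on |charge| < 1e−4 or an interval below 1e−12 pH
  units; compositions with no sign change on [0, 14] (e.g. no basic
  group) are rejected rather than clamped.
* Matching ties are broken deterministically (error, then modification
  count, then sequence) so reports are byte-stable across runs.
* Empty inputs are defined results, not errors: an empty peak list gives
  an all-unmatched report with zero coverage; an empty candidate set
  leaves peaks unmatched; a chain without cysteines yields no linkable
  species; the empty no-core glycan is bare water.
* A modification applied more times than it has eligible residues is an
  error naming the modification and sequence.
* Problem sizes throughout tests and examples are desk-scale: chains of
  ~200 residues, dozens of peptides, a 10-composition library, 20
  replicates for stochastic properties — the whole suite runs in well
  under a minute.

## Known limitations

* No MS/MS scoring: fragment confirmation counts matched b/y ions; it is
  not a probabilistic search engine.
* Intensities are pass-through; nothing is quantified from them beyond
  ranking.
* Glycan compositions are compositional only — no isomers, linkages, or
  structures; sialylation's pI effect is a count of carboxyl groups.
* The pI model ignores electrostatic interactions between groups and
  conformational effects; CE-measured pI of a folded glycoprotein can
  deviate from any composition-based prediction.
* One protease (trypsin) plus a no-cut rule; other specificities would
  be a small extension of `protease_rule()`.
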