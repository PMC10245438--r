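---
title: "Methods: dimer geometry, interface contacts and ensemble metrics for ApoE self-association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer geometry, interface contacts and ensemble metrics for ApoE self-association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packinglens)
```

## The scientific problem

Apolipoprotein E exists in three common isoforms that differ at positions
112 and 158; the AD-associated ApoE4 carries R112 where ApoE3 carries C112.
In crystals of the lipid-free N-terminal four-helix-bundle domain (NTD,
residues ~1-167, helices N1, N2, H1-H4), pairs of chains form a recurring
"dimeric unit" that stacks into crystallographic fibrils, and the shape of
that unit differs between isoforms: ApoE2/ApoE3 lattices pack the two
chains T-shaped, ApoE4 lattices pack them V-shaped. The single C112R
substitution propagates - a new intra-chain R112-E109 salt bridge,
repositioning of R61, destabilisation of the H2-H3 interaction, a change in
Q123 orientation - into a different tilt of one chain against the other,
while the core self-association interface (R38 and R145 of chain A against
E45 and E49 of chain B, with W34 nearby) is conserved. `packinglens`
implements the quantitative machinery of that structural comparison:
everything is phrased as measurements on coordinate files, so the same code
runs on deposited crystal structures, on modelled dimers, and on synthetic
ground-truth constructions.

This vignette records how each quantity is defined, which numerical choices
were open and how they were resolved, what the synthetic generators emulate,
and what the tests do and do not establish.

## The inter-chain angle and T/V classification

For each chain the mass-weighted inertia tensor about the center of mass is
diagonalised; eigenvalues are sorted ascending. The **long axis** is the
smallest-moment eigenvector. Where a source describes "the principal axis"
without naming which, only the long axis of an elongated four-helix bundle
yields a shape-meaningful inter-domain angle - the other two eigenvectors
describe the bundle cross-section - so that reading is adopted.

Eigenvectors are signless, but distinguishing 100 from 80 degrees requires
oriented axes. Each axis sign is fixed against the chain's own
N-terminus-to-C-terminus Calpha vector (first to last Calpha). This is
chain-intrinsic (no reference to the partner chain or the lattice),
deterministic, and makes obtuse T angles reproducible. The inter-chain
angle is then `arccos` of the dot product, in [0, 180] degrees.

Classification uses a single boundary, default **90 degrees** (T at or
above, V below; the boundary is inclusive on the T side so exactly 90
classifies T). The exemplar angles are ~100 and ~75 degrees; 90 is their
midpoint with margin on both sides. The boundary is a parameter
(`t_v_boundary`), constrained to (75, 100) because values outside that
window could not separate the two observed packings at all.

Two weighting modes exist: mass weighting over all heavy atoms (default -
"center of mass" and "inertia" imply mass weighting) and an unweighted
geometric mode usable on Calpha-only subsets for sensitivity analysis.
Hydrogens are ignored everywhere (crystal structures lack them), HETATM
records are parsed but excluded from geometry.

## Crystallographic mate search

A coordinate file's CRYST1 record gives the unit cell; REMARK 290 SMTRY
records give the crystallographic symmetry operators. In the file format
those operators act on orthogonal Angstrom coordinates; internally they are
stored in the fractional basis (rotation conjugated by the
orthogonalization matrix, translation in cell fractions) because lattice
translations are integer shifts there. The orthogonalization convention is
the standard PDB one: crystallographic `a` along Cartesian x, `b` in the
xy-plane.

`find_crystal_dimers()` applies every operator combined with every lattice
translation in a +-1 shell (parameter `mate_search_translations`;
contacting mates in molecular crystals lie within adjacent cells), skips
the identity-with-zero-translation copy of the chain itself, prunes mates
whose center-of-mass distance exceeds twice the chain radius plus the
contact cutoff, and keeps mates with at least one inter-chain heavy-atom
pair within `contact_cutoff` (4.5 Angstrom). Each surviving mate is
reported with its angle, T/V label, interface arrangement label and contact
count, sorted by descending contact count with a lexicographic tie-break on
operator label so output order is deterministic. Structures without
operators but with two or more chains fall back to asymmetric-unit chain
pairs. Whether a given deposited entry's dimeric unit arises from a
crystallographic or a non-crystallographic relation cannot always be known
in advance; crystallographic mates are searched by default and
asymmetric-unit pairs cover the other case.

## Interface contacts, arrangement, clashes

Distance conventions (all between heavy atoms, all configurable):

| quantity | default | rationale |
|---|---|---|
| salt bridge | 4.0 A | conventional charged-group N...O distance |
| generic/polar contact | 4.5 A | conventional heavy-atom contact shell |
| clash | 2.4 A | ~0.6 x summed van der Waals radii of C/N/O |

Salt bridges pair basic-group nitrogens (Arg NE/NH1/NH2, Lys NZ, His
ND1/NE2) with acidic-group oxygens (Asp OD1/OD2, Glu OE1/OE2, C-terminal
OXT). Histidine is included as potentially basic because its protonation
at crystallisation pH is unknown; inclusive reporting with labelled kinds
beats silent omission. An intra-chain mode supports the R112-E109 /
R61-E109 comparisons. Contacts where both nearest atoms are N/O are
labelled `polar_contact`, others `heavy_contact`; the D153-Q46 interaction
seen in V-type structures is therefore reported as a polar contact rather
than guessed to be ionic.

The **arrangement label** captures the interface sub-classification that
distinguishes the intermediate state: T-like when any Q123 side-chain heavy
atom sits within the contact cutoff of any W39/T42 heavy atom across the
interface (evaluated in both chain-role assignments), else V-like. Some
lattices pack at a V angle while keeping the T-like Q123 arrangement; the
two labels are deliberately independent measurements. When the diagnostic
residues are absent the label is `undetermined` with a warning rather than
a guess.

Clashes are reported per residue pair with the minimal atomic distance -
the quantity needed to show that a full-length chain cannot be superposed
onto both chains of a dimeric unit without its N-terminal helices running
into the partner.

## Helix metrics over ensembles

* **Kink angle**: the planar angle at the middle Calpha of a residue
  triplet, default 95-106-117 spanning helix H3; 180 = straight. On an
  ideal helix the Calpha trace is a spiral of radius ~2.3 Angstrom, so even
  a perfectly straight helix reads slightly below 180 depending on the
  phase relation of the triplet; with 11+11 spacing the deviation is ~0.4
  degrees, and the tests allow +-2.
* **chi1**: the N-CA-CB-gamma dihedral (gamma = CG except Ser OG, Thr OG1,
  Cys SG, Val/Ile CG1), IUPAC sign convention (cross-checked against
  bio3d's torsion code), mapped to **[0, 360)** rather than [-180, 180)
  so the two W34 rotamer populations read ~180 ("flip-in") and ~300
  ("flip-out") without a seam between them.
* **Histograms**: default bin width 10 degrees anchored at 0 - fine enough
  to separate the 180/300 populations, coarse enough that a few hundred
  frames fill bins. Values are snapped to a 1e-6 degree grid before
  binning so states constructed exactly on a bin edge land
  deterministically. chi1 is binned on the circle; the reported mode is
  the centre of the most populated bin.

## Secondary structure

Assignment follows the Kabsch-Sander electrostatic H-bond model: the amide
hydrogen is rebuilt geometrically (1.01 Angstrom from N along the sum of
the N-C(prev) and N-CA unit vectors; the segment-initial residue has no
donor, proline never donates), the bond energy is

```
E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   kcal/mol
```

with a bond called at E < -0.5 kcal/mol. n-turns (acceptor i, donor i+n,
n = 3, 4, 5) define G/H/I helices by the two-consecutive-turns rule
(priority H > G > I), isolated turns are T, everything else is C. Strand
and bridge detection is deliberately omitted (coded C): ApoE is an all-alpha
protein and the quantity of interest is helical content; the beta machinery
would add cost without coverage. Chains are split into segments wherever
consecutive Calphas exceed 4.5 Angstrom, and residues missing a backbone O
are unassignable (C).

Binned content: snapshots (optionally strided) are split into `n_bins`
contiguous equal groups, remainder to the last bin; per residue, bin and
code the mean fraction and its SEM across the bin's snapshots are reported.
One-frame bins are legal but degenerate (SEM 0 with a warning).

## HDX residue mapping

A residue takes the average % deuteration of all **high-confidence**
peptides covering it; residues with no high-confidence coverage fall back
to the average over **medium-confidence** peptides; **low-confidence
peptides are never used**; uncovered residues are missing, not zero.
Peptide uptake is assigned uniformly to every residue of the span,
including the first residues: proteolytic-fragment conventions that exclude
one or two N-terminal residues per peptide vary between processing tools,
so exclusion is exposed as a flag (`n_term_exclusion`, 0-2) and defaults to
0. Uptake values are taken as given - no back-exchange correction is
attempted because the correction applied upstream is tool-specific.
Cross-timepoint summaries average the (up to three) timepoint values per
residue with SEM; a residue present at a single timepoint reports its value
with SEM undefined rather than a fake zero. Export writes residue means
into the PDB B-factor column (two decimals, sentinel for missing residues
plus a sidecar list), the conventional channel for structure colouring.

## Trace filtering

The aggregation traces are smoothed with an **8th-order Butterworth
low-pass at normalized passband 0.03183** (fraction of Nyquist), applied
forward-backward so the net filter is zero-phase with squared magnitude
response. The original processing used a proprietary minimum-order IIR
design whose ripple/stopband details are not recoverable; an 8th-order
Butterworth meets the stated passband with >100 dB attenuation one decade
up, comfortably beyond the 20 dB the tests require, and has no passband
ripple to distort the sigmoid plateau.

Numerically the filter is realised as four cascaded biquads
(second-order sections) derived analytically from the analog prototype
poles via the bilinear transform, each normalised to exact unit DC gain.
At this low a cutoff the single 8th-order transfer function is
ill-conditioned (observed DC errors ~1e-3 through a generic filtfilt at
order 8); the cascade with steady-state initial conditions and odd-reflection
edge padding passes constants through to ~1e-13. The order-2 section is
verified against `signal::butter` coefficients in the tests. Replicate
averaging is a point-wise mean over identical grids (optional linear
interpolation onto the first grid), with a point-wise SD channel.

## Synthetic generators: what they emulate, and what they do not

The generators produce the ground truth every measurement is tested
against:

* `make_helix()` builds full backbones by sequential internal-coordinate
  placement (NeRF) from phi = -57, psi = -47, omega = 180 degrees. Rise
  (~1.5 A/residue), twist (~100 degrees/residue) and Calpha radius
  (~2.3 A) are *emergent* from those dihedrals and are verified as
  properties rather than taken as inputs - they cannot be prescribed
  independently of phi/psi. Side-chain heavy atoms are built from ideal
  rotamer internal coordinates only for the residue types the analyses
  need (Trp, Gln, Glu, Asp, Arg, Lys, Thr, Ser, Cys, Val, Ile, His);
  other positions are poly-Ala with a CB. Chirality follows the
  L-convention (improper N-C-CA-CB = +120 degrees, checked against CCD
  ideal residues).
* `make_dimer_at_angle()` rotates a copy of the monomer about an axis
  through the chain's C-terminal Calpha (a fixed, documented choice of
  contact point mimicking end-to-side packing) perpendicular to the long
  axis, then slides it along its own axis to a prescribed nearest-atom gap
  (root-finding on the minimum pair distance). The construction leaves the
  axis directions exact, so the measured angle must match the requested
  one to within numerical tolerance - this is the parameter-recovery
  oracle for the geometry module.
* `make_symmetry_crystal()` encodes the same transform as a symmetry
  operator with a large cubic cell (200 A default) so lattice-translated
  copies stay out of contact and exactly one mate is recoverable.
* `make_ensemble()` samples discrete conformational states (chi1 rotamers,
  kink angles, or local unfolding of a residue window rebuilt with
  extended phi/psi) with prescribed weights plus 0.05 A Gaussian
  coordinate jitter, recording the drawn state sequence.
* `make_hdx_peptides()` turns a per-residue uptake profile into peptides
  whose uptake is the span mean plus Gaussian noise; `make_sls_trace()`
  produces a logistic sigmoid plus white noise on a uniform grid.

All generators are bit-reproducible under a fixed seed.

What passing these tests shows: the measurements recover known geometric
and statistical ground truth, respect their invariances (rigid motion,
linearity, tier dominance, cutoff monotonicity), and handle edge cases as
documented. What they do not show: agreement with real crystallographic
data (which has conformational heterogeneity, alternate locations beyond
one site, solvent, and non-ideal helices), with real exchange kinetics
(EX1/EX2 behaviour, back-exchange), or with force-field-scale
conformational sampling. The crystallographic comparison against the
deposited ApoE entries runs whenever those files are supplied under
`inst/extdata/`; they are not redistributed with the package.
Simulation-scale population values (microsecond dissociation times,
isoform helicity differences from adaptive sampling) are out of scope
entirely; the ensemble tests instead verify that the machinery resolves
constructed populations of the same magnitude (e.g. kink modes ~7 degrees
apart).

## Problem sizes and numerical conventions

Test and acceptance runs use 30-130 residue helices, 100-1000 frame
ensembles, 250 frames for binned content, traces of 800-4000 samples -
sizes chosen so the whole suite completes in about a minute while leaving
every statistical tolerance (binomial error on state masses, SEM claims)
non-trivially exercised.

Further conventions, for completeness: author residue numbering is the
only numbering anywhere (every residue citation in the field uses it);
alternate locations keep the highest-occupancy conformer with ties to the
first encountered, overridable per conformer label; occupancies are clamped
to [0, 1]; angles at bin edges are assigned to the upper bin (left-closed
bins); the T/V boundary is T-inclusive; empty contact lists are valid
results, not errors; degenerate inertia tensors (collinear atom sets) and
cells whose angle combination gives non-positive volume raise errors rather
than returning numbers.

## Known limitations

* PDB fixed-column format only; no mmCIF. Entries too large for PDB
  serial/coordinate fields are out of scope.
* Secondary structure: helix/turn classes only; any strand content is
  reported as coil.
* The interface arrangement label depends on the presence of the
  diagnostic residues (Q123, W39, T42); truncated or mutated constructs
  yield `undetermined`.
* HDX mapping operates on peptide-level uptake tables; raw spectra,
  peptide identification and bimodal (EX1) envelope analysis are upstream
  of this package.
* The trace filter assumes uniform sampling (1% jitter tolerance) and
  refuses otherwise rather than silently resampling.
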