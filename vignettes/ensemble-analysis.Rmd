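---
title: "Analysing conformational ensembles of phosphorylated disordered peptides"
author: "idpens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing conformational ensembles of phosphorylated disordered peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpens)
```

# Scope and model

Intrinsically disordered peptides (IDPs) have no single native structure;
they are described by conformational ensembles — collections of frames, each
a set of Cartesian coordinates. `idpens` analyses such ensembles the way the
molecular-simulation community does for phosphorylated IDPs: global size
observables and their statistical errors, small-angle scattering
representations, residue contacts and salt bridges, secondary structure with
polyproline II (PPII) content, free-energy landscapes over principal
components, and sequence charge-patterning metrics. A synthetic-data module
generates ensembles with known ground truth so that every stage is testable
without any simulation data.

Phosphorylation enters in two places: the fixed-charge model (phospho-Ser/Thr
carry −2 e at physiological pH, Asp/Glu −1, Lys/Arg +1, His 0), and the
salt-bridge chemistry (phosphate oxygens as hydrogen-bond acceptors).
No charge-regulation or pKa model is included — charges are fixed, which is
a stated limitation shared with fixed-charge force-field simulations.

# Size observables and error estimation

`radiusOfGyration()` is the mass-weighted RMS distance to the centre of mass;
`endToEnd()` measures the distance between terminal anchors. Trajectory tools
differ in which atoms anchor the end-to-end distance, and the convention is
rarely reported; we default to backbone N of the first residue to backbone C
of the last, offer `caca` as the alternative, and record the choice in the
result, so either convention can be reproduced explicitly.

Frames from molecular dynamics are serially correlated, so the naive standard
error of a mean is too small. `blockError()` implements Flyvbjerg–Petersen
blocking: block means are formed at successive pair-averaging levels and the
plateau of the block-mean standard error estimates the true error. The
plateau rule — the first level whose estimate moved by less than 5% over two
successive doublings — is a deliberately simple, deterministic criterion; when
no plateau appears the maximum-level estimate is returned flagged as
unconverged. On unit-variance white noise of length 4096 the plateau must
recover 1/64; on AR(1) series the closed form
`sqrt((1+rho)/(1-rho))/sqrt(n)` is the oracle. `seriesAutocorrelation()`
returns the normalized ACF and the integrated correlation time truncated at
the first negative ACF value — the standard positivity truncation, chosen
because summing noisy ACF tails destroys the estimate.

`percentDifference()` rounds half away from zero to integers because
published force-field comparison tables print integer percentages; the
bundled `sizeReferenceTable()` carries the published ensemble means this
utility is exercised against.

# Scattering

`debyeIntensity()` evaluates the orientationally averaged Debye double sum
over scattering centres, frame by frame, in C++. The default form factor is
one unit-weight bead per residue centre of mass: hydration-shell contrast and
atomic excluded volume are deliberately out of scope (they belong to
dedicated tools such as CRYSOL), and bead-level curves are sufficient for
size and Kratky-shape comparisons of flexible chains. The analytic oracle is
the Gaussian-chain (Debye-function) curve `2(exp(-x)+x-1)/x^2`,
`x = (qRg)^2`: a 100-bead freely jointed chain ensemble must match it within
3% for `qRg <= 3`.

`guinierRg()` iterates an unweighted fit of `ln I` against `q^2` on the
window `q*Rg < 1.3`, starting from the ten lowest-q points, until Rg moves
by less than 1%. For globular particles this is the textbook recipe; for
flexible chains the `1.3` window extends beyond the strict Guinier regime
and the fit *systematically underestimates* Rg by about 6% (an exact
property of the Debye function, not a sampling artifact — weighting the fit
only shaves a fraction of a point off). The window is exposed as `qRgMax`;
at 1.0 the bias is below 4%. We keep 1.3 as the default because it is the
convention the field's tooling uses, and document the bias rather than hide
it.

`dimensionlessKratky()` returns `(qRg, (qRg)^2 I/I0)`; Gaussian chains
plateau at 2, globular particles peak near (1.7, 1.1). Whether `I0` comes
from Guinier extrapolation or the lowest-q point is a user choice; Guinier
is the default.

`chi2Fit()` fits `I_ref ~ f*I_obs + c` by minimising the per-point
chi-square with Nelder–Mead after linear interpolation of the calculated
curve onto the reference grid — the procedure used when comparing computed
and experimental curves. The normalisation prefactor is read as `1/N`
(the symbol in the defining equation denotes the number of points); a
`norm = "n-1"` flag provides the other reading so results are comparable
either way. Because `I_obs >> 0` makes `f` and `c` strongly correlated, the
simplex runs in a centred parametrisation `(f, c + f*<I_obs>_w)`; the
closed-form weighted least-squares solution is computed alongside and stored
in the result as a cross-check (the two agree to ~1e-8 relative in the
acceptance runs). Two-column reference files have no error column; the
`sigmaPolicy` options are a constant sigma of 1 (default) or sigma
proportional to the reference intensity.

# Contacts and salt bridges

A residue contact is defined as a minimum inter-atomic distance (hydrogens
included) below 0.4 nm, strict inequality; `contactMap()` reports per-pair
frame fractions against a brute-force recount oracle. Salt bridges are
detected as hydrogen bonds between donor and acceptor atom sets using the
distance–angle criterion `r_DA < 0.33 nm − 4.4e-5 nm/deg^2 * theta^2`, with
`theta` the H–donor–acceptor angle. The criterion's constants are exposed in
`hbondCriterion()` because the method is cited by reference in the
literature more often than printed; auditability requires them to be visible
and overridable. Occupancy is reported at residue-pair granularity (any
qualifying atom pair counts), matching how salt-bridge probabilities are
plotted, with blocking errors on the per-frame indicator. His is excluded
from the donor set by default (ambiguous protonation at fixed charges) and
can be enabled.

# Secondary structure

`assignDSSP()` implements the Kabsch–Sander rules: the electrostatic
hydrogen-bond energy
`E = 0.084*332*(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a −0.5
threshold, n-turns for n = 3, 4, 5, minimal helices from two consecutive
turns, bridges/strands from the parallel and antiparallel patterns, bends
above a 70° five-residue direction change, and the priority
H > E > B > G > I > T > S > C. Missing amide hydrogens are reconstructed
0.098 nm from N, trans to the preceding carbonyl — the standard DSSP
convention, which makes the module usable on heavy-atom-only input.

`extendPPII()` adds the polyproline II extension: residues still irregular
whose (phi, psi) lie in [−104°, −46°] × [116°, 174°] for at least two
consecutive residues are relabelled P. The window bounds and run length
follow the PPII-assignment literature and are configurable, since the
parameterisations in circulation differ slightly; only C residues are
eligible, so the extension can never reduce helix, strand, turn or bend
content. `ssSummary()` reports the published grouping — helix (H+G+I),
strand (E+B), turn, bend, PPII, irregular — whose fractions sum to one by
construction.

The ideal-geometry backbone builder makes these rules testable: with
canonical bond lengths/angles (N–CA 0.1458, CA–C 0.1525, C–N 0.1329 nm;
111.2°/116.2°/121.7°) an (−57°, −47°) chain yields i→i+4 bonds at
−2.1 kcal/mol and interior H; (−49°, −26°) yields i→i+3 bonds and G;
(−75°, +145°) yields no backbone bonds and P after the extension.

# Free-energy landscapes

The landscape pipeline follows the grid-based conditional-free-energy
approach used for simulation ensembles: superpose all frames onto the
central structure, PCA on backbone Cartesian coordinates, Gaussian KDE of
the first two projections, `F = −ln(rho/rho_max)` in RT units, steepest
ascent on the density for basins.

The "central structure" is defined here as the RMSD medoid (the frame with
minimal mean Kabsch-RMSD to all others), computed on a deterministic evenly
spaced subsample capped at 2000 frames; the term is used without definition
in the simulation literature and the medoid is the natural deterministic
reading. The backbone atom set is N, CA, C, O ("backbone atoms" is rarely
qualified; including O makes turn/PPII differences visible); PCA is
unweighted by default with mass weighting as an open flag. Shared-basis mode
concatenates two ensembles, computes one basis and projects each separately,
so two force fields (or salt conditions) live on directly comparable axes.

KDE uses a product Gaussian kernel with Scott's rule per dimension
(`sd * n^(-1/6)`), a 150×150 grid padded 10% per axis, and a 10 RT cap with
masked cells beyond — grid and cap chosen at the resolution scale of
published landscape figures, none of which state their own. Basins follow
steepest ascent over the 8-neighbourhood with ties broken toward the lower
linear cell index (the cited basin method is grid hill-climbing; exact tie
rules are unstated, so ours is deterministic by construction). Minima are
classified in the ≤1, ≤2, ≤3 RT bands used by the figure markers. One
practical caveat the tests encode: with large samples, isolated outlier
points can form unmasked islands below a 10 RT cap and appear as spurious
shallow basins; analyses that need a clean basin count should use an
explicit bandwidth and a tighter cap (the two-population oracle in the
acceptance suite uses bandwidth 0.25 and a 6 RT cap).

# Sequence charge patterning

`chargeFractions()` and `kappaCharge()` compute FCR, NCPR and the
charge-segregation parameter kappa with phosphorylated residues equalized to
negatively charged residues (sign −1 in the patterning; the −2 e magnitude
remains in the charge model). Kappa averages, over blob sizes 5 and 6, the
mean squared deviation of the windowed charge asymmetry
`sigma = (f+ − f−)^2/(f+ + f−)` from its sequence value, normalised by the
most segregated arrangement of the same composition and clipped to [0, 1].

The normaliser is where the open design lives. We take "most segregated" to
mean block arrangements — a positive block and a negative block with the
neutral residues split in all possible ways between front, middle and end —
and maximise delta over that family. This extends the minimal
three-candidate recipe (neutrals before, after, or split at the ends), which
we found insufficient for some neutral-containing compositions. It is *not*
the same as maximising over all permutations: for sequences barely longer
than the blobs, arrangements with charges at both ends make every window
extreme and exceed every block arrangement (at length 6 with two positive
and four negative residues, "+----+" beats "++----" by a factor of 1.8).
Normalising by the permutation supremum would make the canonical segregated
block sequence score below 1, contradicting the definition of kappa as "1
for the most segregated sequence"; we therefore keep the block-family
normaliser, which is also what dedicated sequence-patterning calculators
use. The acceptance suite documents this divergence explicitly at lengths
6–10.

# The synthetic-data module

`generateIdealChain()` produces freely jointed chains — i.i.d. uniform bond
directions at fixed bond length (0.38 nm, the CA–CA spacing of a trans
peptide) — whose `<Ree^2> = (n−1)b^2` and `<Rg^2> = b^2(n^2−1)/6n` make
size, scattering and PCA stages testable against closed forms. Bead mass
defaults to 110 amu (an average residue); only mass ratios matter.
`buildBackbone()` places N, H, CA, C, O per residue by NeRF internal
coordinates from (phi, psi), giving exact dihedral round trips for
secondary-structure tests. `plantContacts()` imposes target contact
fractions by stratified resampling over joint contact patterns
(largest-remainder apportionment of the product distribution), which
preserves every frame's coordinates exactly and errs by at most one frame
per stratum; biased dynamics would be slower and approximate.
`synthesizeReferenceCurve()` wraps a curve in an affine map plus Gaussian
noise to emulate an experimental reference for the chi-square fit.

What the generators deliberately do not emulate: excluded volume, chain
stiffness beyond the fixed bond length, solvent, electrostatics, or any
force-field energetics. Passing the oracle suite therefore shows the
*analysis* machinery is correct, not that any force field reproduces real
peptides — the published comparisons the package reproduces arithmetically
(the percentage-difference table) came from microsecond simulations that are
out of scope at desk scale. Problem sizes in the tests (for example 5000
frames of a 100-bead chain for the scattering oracle, 65536 points for the
AR(1) blocking oracle) were chosen as the smallest that leave the analytic
comparisons clearly outside sampling noise.

# Numerical and I/O conventions

Coordinates are nm everywhere in memory; PDB files are Angstrom on disk and
converted at the boundary. Residue indices are 1-based at the user surface.
Scattering momentum transfer is nm^-1, with `q_unit=A^-1` header support
(values multiplied by 10 on input). The PDB reader is a strict fixed-width
parser that rejects truncated files, reports the line of a malformed record
and names the frame with a deviating atom count; DCD reading is available
through bio3d when installed. Multi-frame PDB writing uses MODEL/ENDMDL
records with standard atom naming. All generators are bit-reproducible
under a fixed seed, and seeded code restores the caller's RNG state.

# Known limitations

* Fixed charges; no pKa/charge regulation (phospho pKa ≈ 6 means the real
  charge fluctuates between −1 and −2 e near physiological pH).
* Bead-level scattering only; no hydration shell or excluded-volume
  contrast, so absolute comparison with experimental SAXS intensities is out
  of scope (the chi-square fit against user-supplied reference curves is the
  supported route).
* The window-1.3 Guinier default underestimates flexible-chain Rg by ~6%
  (documented above).
* The secondary-structure module implements the core Kabsch–Sander rules;
  rarely exercised edge cases of full DSSP (chain breaks, alternate
  locations, multi-chain bridge partners) are not modelled.
* Basin assignment is grid-based; basins narrower than the KDE bandwidth or
  the grid spacing merge.
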