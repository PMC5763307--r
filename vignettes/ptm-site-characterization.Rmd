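---
title: "Structural characterization of PTM sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural characterization of PTM sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptm3d)
```

# The problem

A post-translational modification (PTM) is identified experimentally as a
residue position in a protein sequence, usually with a short flanking
peptide. Its biological consequences, however, are three-dimensional: whether
the modified group sits on a solvent-exposed surface, which residues surround
it in space, whether their side chains point toward it, and whether the site
lies on a protein–protein interface or near a bound drug. `ptm3d` places PTM
sites onto PDB-format structures and computes exactly those quantities.

This vignette documents the models, the numerical choices and the
limitations; the README shows the user-facing workflow.

# Site-to-structure mapping

Mapping is by exact substring identity: the flanking peptide (a 21-mer by
default, the convention of peptide-centric PTM databases; truncated windows
at protein termini are matched as the shorter literal string) is searched in
the chain sequence derived from coordinate records, not from SEQRES. Two
consequences are deliberate:

* Sites falling in crystallographically unresolved regions return `none`,
  because the residues simply are not in the derived sequence. An occurrence
  that would span a numbering gap (a disordered loop) is rejected: residue
  numbers inside a match must be consecutive in author numbering (an
  insertion-coded successor also counts as consecutive).
* Peptides occurring more than once are reported `ambiguous` and never
  assigned, preferring reproducibility over coverage. Overlapping repeats are
  counted (a lookahead search), so low-complexity windows cannot silently
  produce a "unique" first hit.

Author numbering (PDB residue number plus insertion code) is the coordinate
convention everywhere, matching how structural biologists name residues.
Modified residues in coordinates (SEP, TPO, PTR, MSE, ...) are translated to
their parent one-letter code so that a phosphoserine in the crystal still
matches a serine-centered peptide.

# The five site properties

## Radial amino-acid composition

For radii 2–12 Å (cumulative spheres, not shells — per-shell values are
recoverable by differencing), a neighbor residue is counted at radius *r*
when its Cα lies within *r* of the site's reference point. The reference
point is the PTM **target atom** — the side-chain atom the modifying group
attaches to (ND2 for N-glycosylated Asn; OG/OG1/OH for phospho-Ser/Thr/Tyr;
NZ for acylated Lys; SG for Cys chemistry), falling back to Cβ then Cα when
unresolved — because the modified atom is the site's functional locus. A
`reference = "ca"` switch gives plain Cα–Cα counting. The substrate residue
itself is excluded; waters and non-protein heteros never count. The same
neighborhood is split into acidic (D, E), basic (K, R, H) and neutral
residues; histidine is counted basic by convention, and the classification
tables are exported so this is inspectable.

## Side-chain orientation

For substrate *p* with target-atom position $X_p$ and neighbor *k*:

$$S_k = X_p - X_k^{C\alpha}, \qquad V_k = X_k^{F} - X_k^{C\alpha}, \qquad
\theta_k = \arccos\frac{S_k \cdot V_k}{\lVert S_k\rVert\,\lVert V_k\rVert}$$

where $X_k^{F}$ is the neighbor's terminal **functional atom** (OG for Ser,
NZ for Lys, NE2 for His, ... — the full 20-residue table is returned by
`functional_atom_table()` and is user-overridable, since the choice of
terminal atom is a convention rather than a law). A neighbor is functionally
oriented toward the site when $\theta_k < 80^\circ$, strictly: at exactly
80° the flag is `FALSE`. Glycine has no side chain; its records carry
`theta = NA` and are never functional. The arccos argument is clamped to
[−1, 1]; a zero-length vector (coincident atoms) is an error rather than a
silent 0°. The angle is invariant under rigid motion and under rescaling of
either vector, and the implementation is cross-checked against the
numerically robust `atan2(|S × V|, S·V)` form to 10⁻⁹ degrees.

The target-atom table generalizes the orientation construction from
N-glycosylation to the other supported PTM chemistries (each type–residue
pair has exactly one entry); this generalization is an extrapolation of the
same geometric idea, and unsupported combinations fall back to Cβ.

## Solvent-accessible surface area

SASA uses Shrake–Rupley sphere sampling: each heavy atom's solvent-expanded
sphere (van der Waals radius + 1.4 Å probe) carries a deterministic
golden-section-spiral point set (960 points by default; no RNG anywhere), and
its SASA is the unoccluded fraction times the sphere area. Radii: C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å; unknown elements are an error naming the
element. Relative accessibility divides by Gly-X-Gly maxima (theoretical
values of Tien et al. 2013), so values slightly above 1 are possible in
extended conformations. The quadrature sphere is oriented in a
molecule-intrinsic frame (built from centroid-to-extreme-atom directions), so
computed areas are invariant under rigid motion of the input to well below
quadrature error; for degenerate clouds (≤ 2 atoms or collinear) the frame
falls back to the laboratory axes. A single isolated carbon reproduces the
analytic sphere area 4π(1.70+1.40)² ≈ 120.76 Ų to quadrature precision.

Ligands and waters are excluded from the protein surface by default. Because
burial by a partner chain is itself informative, the per-site summary reports
SASA both for the full complex and for the site's chain in isolation.

## Secondary structure

A reduced three-state DSSP-style assignment suffices for descriptive per-site
reporting; the full eight-state alphabet is out of scope. Backbone hydrogen
bonds use the Kabsch–Sander electrostatic energy
$E = 0.084 \cdot 332 \cdot (1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})$
kcal/mol with the amide hydrogen reconstructed 1.0 Å from N on the bisector
of the N−C(prev) and N−Cα directions; $E < -0.5$ is a bond. Prolines and
chain-start residues donate nothing. Two consecutive i→i+4 turns assign H to
the four spanned residues; Kabsch–Sander parallel/antiparallel bridge
patterns assign E, with candidate partners enumerated by Cα proximity
(≤ 6.5 Å) so that the "wide" antiparallel pattern — which links residue pairs
that themselves share no bond — is found. Bonding is evaluated on the whole
structure rather than per chain, because sheet partners and interface
strands frequently lie on different chains; a chain argument filters only
the report. Residues with missing backbone atoms are C and flagged.

# Interfaces and drug proximity

**Contacts.** A cross-chain residue pair (both residues inside the supplied
domain ranges) is a contact if any criterion holds: some N–O atom pair
≤ 3.5 Å (hydrogen bond); some charged-group N–O pair ≤ 5.5 Å with one side
acidic and the other basic (salt bridge); some C–C pair ≤ 5.0 Å (van der
Waals). The salt-bridge criterion is restricted to charged-group atoms
(Lys NZ; Arg NE/NH1/NH2; His ND1/NE2; Asp OD1/OD2; Glu OE1/OE2; terminal
OXT): a bare N–O ≤ 5.5 Å rule would subsume every hydrogen bond and inflate
the salt-bridge class, while leaving the contact *count* unchanged since any
kind suffices. A pair may carry several kinds but counts once. Two domains
interact when **more than five** distinct residue pairs are in contact —
read strictly (≥ 6), with the threshold exposed as a parameter because
"more than" versus "at least" is a recurring ambiguity in prose thresholds.
Contact pairs are counted as residue pairs, not atom pairs. A site is
interface-located only by strict membership in the contact-residue set; an
adjacent residue does not qualify.

**Drug association.** Binding-site membership is a transparent heavy-atom
distance criterion on the observed ligand pose: residues with any heavy atom
within 4.0 Å of any ligand heavy atom form the contact set (the default is
declared, not derived — typed 2D interaction diagrams and docking are out of
scope, and observed poses must be present in the input structure). A site in
the contact set is **strong**; otherwise, if its minimum side-chain
heavy-atom distance to the ligand is ≤ 12 Å — the established outer radius
for phosphosite influence on small-molecule binding — it is **weak**; else
none. Both cutoffs are inclusive; glycine uses Cα as its side-chain proxy.
Waters and a configurable blocklist of crystallization additives (SO4, GOL,
PEG, EDO, ...) are never ligands.

# Synthetic fixtures

The builders exist so that every code path is exercised by constructions
whose correct answer is known by geometry, without any database access:

* `build_helix()` / `build_strand()` extend a chain by natural-extension
  (NeRF) placement from ideal internal coordinates (φ = −57°, ψ = −47° helical;
  φ = −139°, ψ = 135° extended; ω = 180°), with idealized side chains for all
  20 residues. The default sequence is a proline-free sweep of the alphabet
  (proline would interrupt the helical donor pattern). Consecutive Cα–Cα
  distances come out at 3.80 Å and the L-configuration is reproduced
  (improper N-CA-C-CB ≈ −122.5°).
* `build_sheet_pair()` creates an antiparallel two-chain pair by rotating a
  strand 180° in-plane and translating it to the inter-strand offset that
  maximizes the number of backbone hydrogen bonds over a deterministic grid;
  the builder fails rather than emit a pair that does not register as
  strand.
* `build_interface()` places one engineered residue pair per request
  (Ala CB···CB for van der Waals, Lys NZ···Gly O for hydrogen bonds,
  Lys NZ···Glu OE1 for salt bridges) with the contact atoms exactly at the
  requested separation and successive pairs 30 Å apart, then verifies by a
  brute-force scan that exactly the requested contacts (and kinds) exist.
* `build_ligand_complex()` aims the ligand along the outward side-chain
  direction of a serine site and iterates the placement on PDB-rounded
  coordinates until the realized minimum side-chain distance lies within
  [d − 0.002, d] of the request — at, never beyond, the requested distance,
  so inclusive-boundary behavior is genuinely probed.
* `build_random_coil()` is a seeded self-avoiding Cα walk with jittered
  N/C/O atoms for neighbor-search oracle tests; the session RNG state is
  saved and restored.

All builders emit PDB text, so parsing and writing are on the path of every
test. What the fixtures do **not** emulate: real packing density, B-factors,
alternate conformations in the wild, crystallographic disorder, or
physically relaxed side-chain rotamers (torsions are idealized anti/gauche).
Passing tests therefore demonstrate correctness of the geometric rules, not
robustness to pathological real-world files beyond the cases tested
(altlocs, gaps, multi-model files, missing atoms).

# Numerical choices and degenerate inputs

* Alternate locations: blank or 'A' preferred, else highest occupancy; ties
  resolved by file order. One conformer per atom, deterministically.
* Multi-model (NMR) files: first model only; no ensemble averaging.
* Hydrogens are parsed but excluded from every distance criterion (all
  criteria are stated on N, O, C atoms); waters are excluded from all
  analyses.
* Neighbor searches run on a cell-list grid with a brute-force reference
  path; the two are asserted equal on random structures. Exact-boundary
  pairs (distance = cutoff) are included by both.
* Resolution filtering (strictly < 2.5 Å, NMR admitted) is opt-in at the
  pipeline level: users may deliberately analyze lower-resolution
  structures, so the filter is a flag rather than silently dropping input.
* Pipeline outputs are byte-deterministic: no RNG after fixture
  construction, stable orderings everywhere, fixed TSV/JSON serialization.

Problem sizes used in the shipped tests and acceptance script — helices and
strands of 8–25 residues, 50 random 20-residue coils for the search oracle,
960-point quadrature — were chosen as the smallest constructions that
exercise each rule's boundary behavior while keeping the default test run
fast.

# Known limitations

* mmCIF, biological-assembly generation and symmetry mates are out of scope;
  the bound ligand pose must be present in the input file (no docking).
* The three-state secondary structure is not bit-compatible with DSSP
  (no 3₁₀/π helices, turns, bends, or β-bulges).
* Domain ranges are taken as given; no Pfam/HMM scanning.
* The functional-atom and target-atom tables are conventions; both are
  exported and overridable, and results that hinge on a particular choice
  should be read with that in mind.
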