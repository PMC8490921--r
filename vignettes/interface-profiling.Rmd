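---
title: "Profiling GPCR-partner interfaces with gpcriface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling GPCR-partner interfaces with gpcriface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcriface)
```

## The problem

G-protein coupled receptors (GPCRs) signal by coupling to intracellular
partners — heterotrimeric G-proteins and arrestins — through an interface
formed by the cytosolic face of the receptor (the ends of the transmembrane
helices TM1–TM7, the intracellular loops ICL1–ICL3, and helix 8) and, on the
partner side, chiefly the G-alpha C-terminal helix H5 plus neighbouring
elements (hns1, S1–S6, h4s6) or the arrestin finger/C/lariat loops. Which
partner a receptor prefers is encoded in the residue-level anatomy of this
interface. `gpcriface` computes that anatomy from complex structures in PDB
format and aggregates it across a family of complexes into consensus
interaction motifs, so that recurring contact patterns (for example a
proline at the ICL2 position 34.50 meeting a hydrophobic patch on H5) become
directly visible and comparable between receptors.

The package deliberately starts from *assembled complexes*. Building the
complexes — homology modelling, docking, refinement, membrane embedding — is
a separate modelling exercise with its own tools and is out of scope here.

## Generic numbering

Interfaces of different receptors can only be compared on a common
coordinate system. For the helices we use Ballesteros–Weinstein (BW)
numbering: within helix X the most conserved residue is the anchor X.50 and
every other residue is numbered by its offset (`3.50`, `3.51`, ...).
Intracellular loop 2 gets the two-digit prefix 34 (it sits between TM3 and
TM4), the other loops 12/23/45/56/67 analogously, and helix 8 the prefix 8.
Partner subdomains (H5, hns1, h4s6, S1–S6, the arrestin loops) are numbered
positionally from their span start: `H5.01`, `H5.02`, ...

Two design choices matter:

* **Anchors are user input.** Identifying the most conserved residue of a
  helix requires a multiple sequence alignment; re-deriving it would drag an
  alignment stack into a geometry tool and make results depend on the chosen
  sequence database. The annotation table (`chain  subdomain  start  end
  anchor`, tab-separated) therefore carries the anchor residue numbers
  explicitly, and `assign_labels()` is purely mechanical. The index origin
  of positional partner subdomains is likewise fixed by where the user
  starts the span.
* **Anchor-free receptor spans fall back to author numbering.** Poorly
  conserved stretches — ICL3 is the canonical case — have no meaningful
  family-wide anchor; residues there keep `chain:resnum` labels, which is
  exactly how such positions are cited in the literature.

## Interface profile

`interface_profile()` runs four passes, each independently callable:

* **Contacts** (`find_contacts`): a receptor-residue/partner-residue pair is
  a contact when the Cα–Cα distance is at most 8 Å. The boundary is
  inclusive; the cutoff is configurable (`run_config(contact_cutoff=)`).
  The implementation is a vectorized cross-distance computation, and the
  test suite holds it equal to a literal double-loop oracle on every
  fixture.
* **Hydrogen bonds** (`detect_hbonds`): a geometric heavy-atom rule — donor
  N/O within 3.5 Å of an acceptor (O, or a histidine ring N) across the
  interface. When the structure carries explicit hydrogens a donor must
  actually bear one and the D–H…A angle must reach 120°; without hydrogens
  every N/O is a potential donor. Both thresholds are configuration
  parameters. This is a deliberately transparent criterion, not an
  energy-based assignment: it is stable, explainable and cheap, which is
  what a fingerprint needs.
* **Salt bridges** (`detect_salt_bridges`): Asp OD1/OD2 or Glu OE1/OE2
  within 4.0 Å of Lys NZ, Arg NH1/NH2/NE or His ND1/NE2 (histidine counted
  as positively charged), either direction. Atom sets and cutoff follow
  common literature convention and are configurable.
* **Surface burial and composition** (`buried_surface`, `composition`):
  buried area is SASA(receptor) + SASA(partner) − SASA(complex), clamped at
  zero against numerical noise. Composition reports per-side percentages of
  each amino acid and of four groups that partition the twenty residues
  exactly — hydrophobic (A,V,L,I,M,F,W,P,G), polar (S,T,C,N,Q,Y), positive
  (K,R,H), negative (D,E) — so group percentages always sum to 100.

SASA is Shrake–Rupley: each atom's sphere of radius r~vdw~ + probe (probe
1.4 Å, water) is sampled and the unoccluded point fraction scaled to the
sphere area. The point set is a deterministic Fibonacci sphere, so repeated
runs are bit-identical — important because the command-line tool promises
byte-identical artifacts for identical inputs. The default 960 points per
atom keeps the isolated-atom error well under 1% (the analytic value
4π(r+1.4)² is a test oracle); 240 points are enough for quick exploratory
work and the count is exposed everywhere. Unknown elements fall back to a
1.8 Å radius with a warning.

## Geometry

`interhelical_distance()` measures either a Cα–Cα distance between two
generic labels or the distance between Cα centroids of two subdomain spans.
The classic use is the cytosolic TM3–TM6 opening that widens upon receptor
activation; because the literature tabulates several different residue
pairs for it, the endpoints are always caller-specified (3.50/6.30 is a
reasonable convention) and nothing is hard-coded.

`superpose()` is the Kabsch algorithm — SVD of the covariance matrix with a
determinant sign correction so only proper rotations are returned — giving
the least-squares rotation/translation and RMSD for model-vs-experiment
comparisons. Exact recovery of known rigid transforms and invariance of the
fitted RMSD under rigid pre-transforms are asserted to 1e-9 and 1e-6.

## Elastic-network flexibility

Coupling rigidifies parts of the receptor; to quantify that without a force
field we use the anisotropic network model (ANM) on Cα atoms: springs of
uniform constant γ connect all Cα pairs within 12 Å, the 3N×3N Hessian is
assembled from −γ(d⊗d)/|d|² super-elements, and its eigenmodes give
harmonic fluctuations. Mean-square fluctuation per residue is the per-node
trace of the Hessian pseudo-inverse, computed by summing 1/λ over the
internal modes; the test suite checks this against an independently
computed Moore–Penrose pseudo-inverse to 1e-8.

Numerical points worth stating:

* Rigid-body modes are identified by an eigenvalue threshold of 1e-6
  relative to the largest eigenvalue, not by taking "the first six", so a
  near-degenerate spectrum fails loudly rather than silently mixing an
  internal mode into the null space. The expected null-space dimension is
  geometry-aware: six for a genuinely three-dimensional node set, five for
  collinear ones (rotation about the axis is trivial — the two-node network
  with its single non-zero eigenvalue 2γ is the closed-form test case).
* A disconnected network (cutoff too small) is refused with the component
  sizes named, since fluctuations of a floating fragment are meaningless.
* ANM units are arbitrary (1/γ), so `delta_fluctuations()` reports the
  complex-minus-monomer change both raw and after per-structure
  normalization by the mean fluctuation; only the normalized delta is
  comparable across structures of different size.

## Consensus across complexes

`build_matrix()` unions the labeled contact pairs of several profiles into
a presence matrix; "interaction present" means at least one contact for the
labeled pair — hydrogen-bond and salt-bridge status ride along as metadata
but are not required, because requiring them would make presence depend on
the least robust part of the geometry. `common_interactions()` keeps cells
present in at least `min_fraction` of the complexes; the default 1.0 is the
strict all-complexes filter used for family-consensus figures.

`format_motif()` renders one subdomain's consensus as a compact string:
residue letters at interacting positions (alternatives across complexes
slash-joined in order of first appearance), `x`-wildcards with multiplicity
for skipped interior positions, fused letters for adjacent single-residue
positions, and generic labels on the first and last interacting position,
joined with en dashes — e.g. `P34.50–V/I–x2–LD34.55` for an ICL2 pattern or
`T/KH5.12–x2–I–I/LH5.16` for an H5 pattern. The dialect (separator
placement, fusing, plain-digit multiplicities) is canonicalized by this
package so motif strings are machine-comparable; published typography of
such motifs varies and is not.

## Synthetic fixtures: what they do and do not show

Every stage is exercised by `make_helix()` / `make_toy_complex()` /
`make_charged_pair()`: ideal α-helices (1.5 Å rise and 100° twist per
residue, Cα 2.3 Å from the axis) with backbone N/CA/C/O and CB, plus
idealized radially-grown side chains for the charged residues only — enough
to give salt-bridge and hydrogen-bond detection real geometry without a
rotamer library. `make_toy_complex()` returns the ground-truth contact set
computed at construction time by an independent brute-force loop, which is
the central integration oracle. Fixture generation is deterministic given
the seed; two runs write bit-identical PDB files.

These are geometric test articles, not physical models: no side-chain
packing, no realistic rotamers or protonation, no membrane. Passing tests
demonstrate that the implemented criteria are computed exactly as specified
— they do not validate the criteria against experimental energetics, and
absolute buried-area or fluctuation values on toy helices should not be
read as biologically meaningful. In the one fixture where idealization
bites — the isolated charged pair, whose stretched side chains put the Cα
atoms ~14 Å apart — tests pass an explicit wider contact cutoff instead of
the 8 Å default; real salt bridges live inside real interfaces where Cα
atoms are close.

Problem sizes throughout the suite (helices of 8–20 residues, 20-complex
contact batteries, 100 consensus trials, 100,000-point surface references)
were chosen so the full suite runs in well under a minute while every
numerical assertion stays at its stated tolerance.

## Configuration and determinism

`run_config()` gathers all thresholds (contact 8 Å, H-bond 3.5 Å / 120°,
salt bridge 4 Å, probe 1.4 Å, 960 surface points, ANM 12 Å / γ=1, consensus
fraction 1.0). The command-line tool (`inst/cli/gpcriface`, subcommands
`profile`, `consensus`, `enm`, `distance`, `superpose`, `fixtures`) accepts
a `key=value` config file overridden by flags, echoes the resolved
configuration into every artifact header, writes no timestamps, and
therefore produces byte-identical outputs for identical inputs — asserted
in the test suite by diffing two complete runs.

## Known limitations

* PDB input only (first MODEL block; highest-occupancy altloc), no mmCIF.
* The Cα contact criterion is the classical coarse definition; it neither
  requires nor checks heavy-atom proximity.
* Hydrogen-bond assignment without explicit hydrogens over-approximates
  donors by design.
* Consensus filtering matches label pairs exactly; it does not collapse
  structurally equivalent positions across partner subfamilies.
* No energetics anywhere: contacts, bonds and bridges are geometric flags.
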