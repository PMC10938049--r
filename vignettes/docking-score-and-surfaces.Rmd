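---
title: "Scoring, pose refinement and surface generation in softdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, pose refinement and surface generation in softdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softdock)
```

softdock is a scriptable toolkit for exploratory rigid-body multi-body
protein–protein docking: given all-atom structures with partial charges
(Tripos mol2), it scores an arrangement of molecules, refines one
molecule's pose by greedy random perturbation, and builds a
Solvent-Excluded-Surface (SES) mesh colored by electrostatic charge.
This vignette explains the model, the tunable parameters, the numerical
choices, and what the validation does and does not establish.

## The binding score

Molecules are rigid. The score of a scene is the sum, over every
unordered pair of molecules, of an interaction energy; intramolecular
terms are constants under rigid motion and are excluded, so a
single-molecule scene scores zero. Between two atoms $i$ and $j$ at
distance $d_{ij}$, two terms contribute:

**Soft van der Waals.** An 8–6 Lennard-Jones potential,

$$E_p(i,j) = 3\epsilon\left(\frac{r_i+r_j}{d_{ij}}\right)^8
           - 4\epsilon\left(\frac{r_i+r_j}{d_{ij}}\right)^6,
  \qquad \epsilon = \sqrt{\epsilon_i\,\epsilon_j},$$

with $r$ the atomic van der Waals radii (Å) and $\epsilon$ the pair well
depth from Berthelot's geometric-mean combination (kcal/mol). Compared
with the common 12–6 form, the $r^{-8}$ repulsion is deliberately soft:
moderate clashes are penalized gently, which keeps an exploratory,
coarsely-posed complex scoreable. The analytic shape is the backbone of
the test suite: the unique minimum sits exactly at contact
($d = r_i + r_j$) with depth $-\epsilon$, the zero crossing at
$d = \tfrac{\sqrt3}{2}(r_i+r_j)$, and the tail decays monotonically to
zero.

**Coulomb electrostatics.** $F(i,j) = 332.0522\,c_i c_j /(E_0\,d_{ij})$
with partial charges $c$ in elementary charge units, the conversion
factor 332.0522 kcal·Å/(mol·e²) expressing the result in kcal/mol, and a
dielectric constant $E_0 = 20$ damping the interaction as implicit
screening. The formula is implemented exactly as written — a single
$d_{ij}$ in the denominator with constant $E_0$ — rather than as a
distance-dependent dielectric $\epsilon(d) = E_0 d$ (which would give an
overall $1/d^2$); the constant-$E_0$ reading matches the printed form
and keeps the unit-input worked example $332.0522/(20\cdot1) = 16.60261$
exact.

Both terms are truncated with a hard cutoff, default 12 Å, applied
symmetrically per atom pair: beyond it a pair contributes exactly zero
(no switching or shifting function — the tests recover the cutoff
operationally by bisecting the zero/nonzero indicator). Below
`min_distance` (default 0.1 Å) the distance is clamped: an interactive
front-end would prevent deep interpenetration with collision handling,
and the clamp is the library's equivalent, keeping scores finite and the
optimizer stable in its place.

### Parameters and their defaults

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 12 | Å | hard truncation of both terms |
| `dielectric` | 20 | — | Coulomb damping |
| `coulomb_constant` | 332.0522 | kcal·Å/(mol·e²) | unit conversion |
| `min_distance` | 0.1 | Å | clash clamp floor |

Per-atom radii and well depths come from an element-keyed table
(`inst/extdata/vdw_parameters.tsv`): Bondi van der Waals radii and well
depths of Amber/GAFF magnitude for C, N, O, S, H, P, plus a default
entry that makes the lookup total (unknown elements warn and fall
back). The table is a documented stand-in, not a claim about any
particular force field's values; it is replaceable by any file in the
same format, and all scores are reproducible given the table. Charges
are never computed: they must come from the mol2 input ("all-atom"
files, hydrogens included and scored like any atom).

### Cell-grid acceleration

The pair sum is restricted through a uniform cell grid with cell edge
equal to the cutoff: each atom of the first molecule needs only the
atoms of the second within the 27-cell neighborhood of its own cell,
which bounds the work per atom by the local density rather than the
partner's size. The grid lives in the second molecule's *local* frame
and query points are transformed into that frame, so rigid pose changes
never require a rebuild. Correctness is not argued but measured: a plain
$O(N^2)$ double-loop implementation (`brute_force_scene_score`) applies
the identical cutoff and clamp, and the accelerated path must agree with
it to ~1e-9 relative on dozens of seeded random scenes. The agreement
residual is floating-point summation order, nothing else.

## Greedy pose refinement

`optimize_pose` is a stochastic hill-climb: each iteration proposes a
random rigid perturbation of the selected molecule's pose — translation
offset uniform in a ball of radius `max_translation_step` (default
1.0 Å), rotation about the molecule's current world centroid by a
uniformly random axis and an angle uniform in `[-max_rotation_step,
+max_rotation_step]` (default 0.1 rad) — and accepts it only if the
scene score strictly decreases. Position and rotation are perturbed
jointly in one proposal. There is no temperature and no annealing: the
procedure is a local refiner of a user-supplied starting arrangement,
not a global search, mirroring its role as the automatic companion to
interactive manipulation. Design choices worth stating:

* **Strict acceptance.** Ties are rejected by default (`accept_equal`
  flips this), so the score trace is non-increasing by construction and
  the final trace entry re-scores exactly.
* **Centroid pivot.** Rotating about the molecule's centroid keeps the
  displacement caused by a rotation step comparable to a translation
  step; rotating about the origin would couple the two scales to the
  molecule's distance from the origin.
* **Determinism.** One seeded RNG stream per call (`seed` in
  `optimizer_config`), saved and restored around the run, so identical
  seeds give byte-identical traces and the caller's RNG state is
  untouched.

The defaults are validated by a parameter-recovery experiment with a
known answer: two single-atom molecules with $\epsilon = 0.1$,
$r = 1.5$ Å and zero charges, started 6 Å apart, must recover the
analytic optimum — separation $3.0 \pm 0.1$ Å, score within 5% of
$-0.1$ kcal/mol — in 2000 iterations.

## Solvent-Excluded Surface

The SES is generated on a voxel grid in two classification passes based
on atom and probe distances:

1. **Accessible interior.** Voxels inside the union of probe-expanded
   atom spheres (radius $r_a + p$, probe $p$ default 1.4 Å, water) are
   marked interior. The grid covers the atom bounding box padded by
   $\max_a r_a + 2p$, so an exterior shell always exists.
2. **Probe placement and signed values.** Interior voxels with an
   exterior 6-neighbor approximate the accessible boundary; each is
   projected radially onto the nearest atom's probe-expanded sphere,
   giving probe centers that lie on the true accessible surface rather
   than at voxel resolution (this projection is what keeps the
   extracted radius accurate at coarse spacings). Every interior voxel
   within reach then receives the value $p - d_{\mathrm{probe}}$, where
   $d_{\mathrm{probe}}$ is the distance to the nearest probe center.

The sign convention is: negative inside the SES (an atom center is at
$\le -r_a$), positive in the solvent-carved region between SES and
accessible surface, and positive outside. The zero level set is the
SES: points at exactly probe distance from the accessible surface. For
an isolated atom this reproduces the atom sphere itself (radius $r$,
not $r + 2p$) — the property the acceptance checks lean on, since the
exact area $4\pi r^2$ is known.

Numerical details chosen here: deep-interior voxels keep a fill value
of $-3h$ (spacing $h$) and exact distances are only computed within
$p + 3h$ of a probe center — the zero crossing always falls in the
exactly-computed band, so interpolated vertex positions are unaffected
while the cost stays proportional to the surface, not the volume.
Exterior voxels hold the constant $+p$; no crossing can involve them as
long as $h \ll p$, which the spacing clamp guarantees.

**Voxel spacing** follows an empirical rule tied to the bounding box,
$r_c = \tfrac{1}{3}(s_x + s_y + s_z)\cdot 10^{-2}$ Å, clamped to
$[0.2, 1.5]$ Å: small molecules get fine grids, large complexes stay
tractable, and degenerate boxes (a single atom) land on the floor. The
clamps are this package's addition; the raw rule alone would request
arbitrarily fine grids for small inputs.

**Mesh extraction** marches the voxel grid with the tetrahedral variant
of marching cubes: each cell is split into the six Kuhn tetrahedra
sharing its main diagonal, and each tetrahedron contributes triangles
according to the signs at its four corners, with vertices placed on
straddling edges by linear interpolation. The decomposition is uniform
across the grid, so face diagonals of neighboring cells coincide and
closed level sets yield watertight, consistently outward-oriented
meshes (checked by edge-sharing counts, Euler characteristic 2 and
positive signed volume on spheres). The tetrahedral table (16 cases)
is small enough to verify by hand, which is why it was preferred over
the classic 256-case cube table; the cost is more, slightly thinner
triangles for the same spacing — immaterial for area and topology, the
quantities validated here (analytic sphere at $h = 0.2$: area within
0.3%).

**Charge mapping.** Each vertex receives the inverse-distance-weighted
mean charge of its $k = 8$ nearest atoms; each triangle the mean of its
three vertex charges. This is a display smoothing, not electrostatics:
it conserves sign near a dominant charge, maps zero charges to a zero
field, and varies smoothly across the surface, which is what the
red–white–blue rendering needs (saturated red at $-q_{max}$, white at
0, saturated blue at $+q_{max}$, linear between, clamped outside).
Meshes export to ASCII PLY (with per-vertex color and a custom `charge`
float property) or OBJ (geometry only).

## Synthetic fixtures

Everything the tests need is generated in code, deterministically from a
seed:

* **Diatomic toy** — two single-atom molecules on the x-axis. Its score
  has a closed form, which anchors the scoring function and gives the
  optimizer a known optimum.
* **Random scenes** — clouds of C/N/O/S/H/P atoms with charges uniform
  in $[-1, 1]$ e (the magnitude range of typical force-field partial
  charges), posed with random rotations in a configurable box. These
  exist to exercise the accelerated-vs-brute-force agreement and the
  rigid-invariance algebra, not to resemble proteins: they have no
  bonds, no excluded volume, no secondary structure, and atoms of one
  "molecule" may interpenetrate. Passing tests on them certifies the
  *mechanics* of the score (cutoff handling, grid completeness,
  additivity, invariance), not docking accuracy on real complexes.

Validation problem sizes: oracle-agreement runs use 50 seeded scenes of
2–5 molecules and at most 2000 atoms total; SES checks use single atoms
at spacings 0.4 and 0.2 Å plus two-atom fused/separated topology cases;
round-trip checks use 100 random molecules of up to 20 atoms. These
sizes make the whole suite run in well under a minute while still
exercising every code path; all of them scale up linearly if a user
wants heavier evidence.

## Known limitations

* The score is a rigid-body interaction estimate only: no solvation,
  entropy, flexibility, or statistical-potential terms; no forces or
  gradients.
* The shipped parameter table is element-keyed; SYBYL-type-resolved
  parameters (distinguishing, say, sp2 from sp3 carbon) would be more
  faithful and can be supplied as a custom table file keyed the same
  way.
* The distance clamp makes deeply clashed poses finite but meaningless;
  the optimizer can traverse them, which is intended (soft potential),
  but reported scores of clashed scenes should not be interpreted.
* The SES generator targets display- and scoring-support quality:
  coarse spacings (near the 1.5 Å clamp ceiling) can merge narrow
  crevices; the probe-center band assumes $h$ well below the probe
  radius.
* mol2 reading is deliberately minimal: MOLECULE and ATOM sections
  only, charges required; bonds and substructures are ignored.
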