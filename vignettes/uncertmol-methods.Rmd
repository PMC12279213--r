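---
title: "Uncertainty-aware inverse molecular design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware inverse molecular design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Inverse molecular design (IMD) asks for a molecule whose properties match a
target vector $p$. The ground truth is the *native forward process* (NFP)
$f$: the expensive physical computation (conformer generation plus a
quantum-chemistry calculation, in the canonical setting) that maps a
molecule to its properties. Because $f$ cannot be inverted directly, a
learned surrogate $\Phi$ stands in for it, and the naive design objective
is

$$x^* = \arg\min_x \, |p - \Phi(x)|.$$

Two failure modes make this untrustworthy. First, the molecule-to-property
map is high-frequency — tiny structural edits cause large property jumps —
so $\Phi$ fits it poorly. Second, unconstrained optimization drives $x$
into regions no training data ever covered, where $\Phi$'s predictions are
confidently wrong. The symptom is *surrogate–NFP misalignment*: the gap
between the design error the surrogate believes and the error the NFP
measures.

`uncertmol` implements a design pipeline built to stay aligned with the
forward process, with four components: a property-organized molecular
latent space (a multi-view VAE), *reacquisition* of surrogate training
pairs, a deep-ensemble surrogate with epistemic uncertainty, and
uncertainty-penalized latent optimization.

# Molecular representation

## A robust string encoding

Molecules are represented primarily as strings over a small symbol
alphabet (SELFIES-style). The package implements its own constrained
derivation engine over the QM9 element set (C, N, O, F; hydrogens
implicit), because the defining property of this representation — *every*
symbol sequence derives to a valence-correct molecule — is the premise
that makes "decode any latent" safe. Design choices:

* Atom symbols carry an optional bond-order prefix (`[C]`, `[=C]`,
  `[#C]`, …). Bond orders are clipped to the valence still available;
  chain derivation stops at a saturated atom.
* `[Branch1]` and `[Ring1]`/`[=Ring1]` read the *next* symbol as an
  overloaded index (its position in the canonical alphabet): branch
  length, or how many atoms back the ring partner sits. Inapplicable
  branches/rings are skipped.
* A sequence that derives no atoms completes to methane, so the validity
  guarantee holds with no exceptions.
* Triple-bond ring closures and branch/ring spans beyond the index range
  are not encodable; the encoder reports this rather than guessing
  (irrelevant at the molecule sizes the package targets).

These semantics are this package's own (the guarantee, not the exact
grammar, is what the method needs). Tokenization pads to a fixed
`max_length` (default 32) with `[PAD]`, and the vocabulary is built from
the training corpus, not the whole grammar, to bound the decoder's output
head.

## Graphs, identity, and the chemistry toolkit

Standard cheminformatics goes through OpenBabel (`ChemmineOB`): canonical
SMILES as the structure identity used by novelty/uniqueness, SMILES
parsing, bond re-perception from raw coordinates, and the molecular
descriptors used by the desk-scale oracle. Graphs keep heavy atoms only
(hydrogens implicit), matching common small-molecule encoders;
coordinates are centered per molecule.

Conformer embedding, by contrast, is implemented in the package: a seeded
distance-geometry construction (ideal bond lengths from covalent radii
scaled by bond order; 1-3 distances from idealized sp/sp²/sp³ angles;
soft repulsion between atoms three or more bonds apart) relaxed by
gradient descent from a seeded random start, with an explicit convergence
criterion — every bond within 0.25 Å of its ideal length — so strained
topologies surface as embedding *failures* rather than silent nonsense
geometry. The reacquisition chain needs its conformer generator to be a
deterministic function of (structure, seed), and general-purpose 3D
builders use unseedable stochastic conformer searches, which is why the
embedder is owned by the package.

# The forward oracle and "stability"

The package's oracle contract is a function `x -> oracle_result` where the
result is either `ok` with a named, unit-labelled property vector or
`unstable` with a reason. Three implementations ship:

* **Descriptor oracle** (default): molecular weight (Da), a logP
  estimate, and topological polar surface area (Å²) — three cheap
  descriptors mirroring the dimensionality and multi-objective structure
  of a HOMO/LUMO/dipole setting without quantum chemistry.
* **Analytic oracle**: $p = Az + b$ on latents directly, for closed-loop
  verification with exact ground truth.
* **External-command adapter**: the contract a quantum-chemistry wrapper
  satisfies (SDF in, JSON properties out; failures surface as
  `unstable`). The package deliberately ships no physics configuration.

A physics oracle can fail to converge on a pathological structure; the
desk-scale mirror of that is built into the descriptor oracle's stability
chain: a molecule is **stable** iff (1) its structure is interpretable in
the constrained representation (supported elements, valences, neutral,
single fragment), (2) a 3D conformer embeds (converges), (3) re-perceiving
connectivity *from the embedded coordinates alone* reproduces the intended
topology, and (4) all descriptors are finite. Step (3) is the load-bearing
one: strained and cumulated motifs embed to geometries that do not support
their own topology and are rejected, exactly the graded failure behavior a
convergence criterion provides. When the oracle receives a *conformer*
rather than a string (as in the perturbation study), one further condition
applies: the given geometry must itself be a near-equilibrium conformer of
the perceived topology (every bond within the embedder's 0.25 Å
tolerance) — a physics stage sees the geometry it is handed, so a
distorted geometry must be able to fail, not be silently repaired by bond
re-perception. Unstable molecules are dropped and counted, never imputed.

# The multi-view VAE

The encoder consumes two linked views — the one-hot token sequence and the
padded, masked heavy-atom graph (element one-hots plus centered
coordinates, pooled per molecule) — fused by concatenation into a diagonal
Gaussian posterior $(\mu, \log\sigma^2)$ (log-variance clamped to
$[-10, 10]$). A molecule whose conformer embedding failed is encoded from
the token view with zeroed graph features and an absence flag. The decoder
maps $z$ to per-position symbol logits, per-slot atom-type scores and
coordinates (non-equivariant, in the input frame), and a separate head
predicts properties from the *sampled* $z$, which keeps that head
meaningful on prior samples later. The training loss is the unweighted sum

$$L = |p - \hat p| + \lVert x_{graph} - \hat x_{graph}\rVert_2^2 +
  \mathrm{CE}(x_{string}, \hat x_{string}) + \mathrm{KL}(q(z)\,\Vert\,N(0, I)),$$

with properties standardized to zero mean/unit variance over the training
set (mixed natural units would otherwise dominate the L1 term), the graph
term masked to real atoms and skipped when no graph exists, and the KL in
closed form. All four weights are configurable but default to 1.

Optimization is AdamW with a cosine-annealed learning rate, batch size 32,
50 epochs by default. All forward/backward passes are hand-written dense
algebra (no autodiff framework is involved); the backward pass is verified
against finite differences in the test suite, and training is seeded and
bitwise reproducible. Decoding is greedy per-position argmax by default
(deterministic designs); sampling decode sits behind a flag.

**Desk-scale training sizes.** The default recipe (50 epochs, batch 32)
is calibrated for corpus sizes in the 10^5 range; on the few-hundred
molecule synthetic corpora used by the package's own studies this amounts
to only a few hundred gradient steps, so those studies train for 300
epochs at learning rate 3e-3 — same optimizer contract, enough steps to
actually organize the latent space. The studies' corpus (200 random
molecules, 12-symbol maximum, latent dimension 16) builds in well under a
minute.

# Reacquisition

The conventional way to train a latent-to-property surrogate pairs each
training molecule's encoded latent with its ground-truth property. Two
problems: molecules the VAE reconstructs imperfectly contribute latents
whose decodings are *different* molecules (label noise in latent space),
and encoded latents cover only the data manifold, not the prior region the
optimizer will search. Reacquisition replaces this: sample $z \sim N(0,
I)$, decode, embed, and label with the oracle, keeping pairs whose oracle
call succeeded (failures counted). The stored property of every pair is
recomputable by re-running decode–embed–label on its latent, and the
dataset carries its own standardization statistics so the surrogate and
the optimizer share one scaling. Duplicate decoded molecules are kept as
distinct pairs: they encode the decoder's many-to-one structure.
The default reacquisition budget is 10,000 pairs; the closed-loop studies
use 2,000 at latent dimension 16.

Datasets serialize as a plain-text directory (latents CSV, properties
CSV, JSONL provenance, JSON manifest). The legacy construction is kept,
flagged `legacy`, as the ablation baseline.

# The ensemble surrogate and epistemic uncertainty

The surrogate is an ensemble of $n = 5$ MLPs (two hidden layers of 64)
with identical structure but different activations — relu, tanh, gelu,
silu, elu — trained with L1 loss in standardized property space. Ensemble
size and the activation list are package choices (standard deep-ensemble
practice); only "identical layers, different activations" is inherent to
the design. Diversity is increased by stochastic gating: at each
mini-batch iteration each member independently takes its AdamW step with
probability $q = 0.3$, so 300 nominal epochs realize about 90
update-epochs per member, each member seeing its own random subsequence
of batches. Gating is per member per iteration (the literal reading of
"at each iteration"); realized update counts are recorded in the training
history.

The mean prediction is $\Phi_{avg}(z) = \frac1N \sum_j \Phi_j(z)$ and the
epistemic uncertainty is the population variance of member predictions,

$$U(z) = \frac1N \sum_j \Phi_j(z)^2 - \Phi_{avg}(z)^2,$$

computed per property in standardized space (clipped at zero against
floating-point negatives; the one-pass form is tested against a two-pass
variance to 1e-10). For multi-property models the scalar aggregate is the
sum over properties — the simplest extension of a formula written for
scalar outputs, and the choice is isolated in one place should a
practitioner prefer a weighted combination.

# Uncertainty-aware latent optimization

A design request asks for targets $p$ (any subset of trained properties),
standardized with the surrogate's statistics. Starting from $z \sim N(0,
I)$, plain gradient descent (learning rate 0.1, 500 steps, cosine
schedule — mirroring the training optimizer contract) minimizes

$$L(z) = \textstyle\sum_k |\Phi_{avg,k}(z) - p_k| + \lambda\, U(z),$$

with $\lambda = 1$ by default ($\lambda = 0$ recovers the naive
objective). Because the surrogate is nonconvex the *best iterate*, not
the last, is returned. A budget of $k$ tries (default 10) restarts from
independent seeds; when an oracle is available the try with the lowest
oracle error is retained (the evaluation-protocol reading), otherwise the
lowest surrogate error — both modes are implemented since the protocol
phrasing admits either. Extra penalties plug in as named callables; the
shipped example is a molecular-mass penalty, implemented decode-and-score
(it has no analytic gradient; it steers best-iterate and best-try
selection), keeping the hook honest about differentiability.

# Evaluation

* **Oracle (NFP) error** — mean absolute error between oracle-computed
  properties of the designs and their targets, natural units, unstable
  designs excluded and counted.
* **Novelty** — share of designs whose canonical id is not in a
  user-supplied reference set (the studies use the fixture corpus).
* **Uniqueness** — share of distinct canonical ids among designs.
* **Misalignment** — $|\mathrm{MAE}_{oracle} - \mathrm{MAE}_{surrogate}|$
  per property: the trustworthiness metric.

All metrics are recomputable from the persisted per-design CSV, which the
tests verify by recomputing them from the file.

## The perturbation study

To show why latents are the right design variable, the study perturbs each
representation minimally and measures what fraction of molecules stay
stable and how much their properties move: Gaussian $N(0, 0.1)$ noise on
one atom's coordinates, one random atom-type change, one random symbol
swap (always decodable, by the robustness guarantee), or $N(0, 0.1)$
noise on the encoded latent followed by decoding. Perturbed geometries are
first re-perceived into a molecule from coordinates alone, then every mode
passes the *same* forward-process chain, so stability percentages are
comparable across modes. The study corpus is screened to oracle-stable
molecules first (a physics-labelled training set is stable by
construction), so the baseline is clean and the reported percentages
measure the perturbation, not the corpus. The expected ordering — latent
perturbations most stable, geometry perturbations least — is asserted
directionally; the magnitudes of a DFT-based pipeline are not
reproducible with a descriptor oracle.

# Synthetic data and what passing tests mean

The fixture generator draws random symbol sequences (lengths uniform on
3..16, atom symbols 3:1 over structural ones so draws are molecule-like),
deduplicates by canonical id, and labels with the descriptor oracle. This
emulates the *shape* of the real setting — a corpus of small organic
molecules with three correlated numeric properties — but not its
distributions: random-derivation molecules are stranger than a curated
quantum-chemistry dataset (the stability screen keeps roughly half), and
descriptor properties are smoother functions of structure than electronic
properties. Closed-loop claims (parameter recovery, the value of the
uncertainty term, reacquisition vs legacy pairs) are therefore verified
on the analytic harness where ground truth is exact; corpus-based runs
verify the machinery end to end, not quantum-chemistry accuracy.

The closed-loop harness confines training latents to a box $[-r, r]^d$
(uniform draws, $r = 1$), uses a random unit-norm linear oracle, and
partitions targets into achievable-in-region (within 0.6 of the box
amplitude $S = \max_{box} |Az|$) and beyond-region (1.05–1.4 $S$; the
boundary band 0.9–1.3 $S$ for the uncertainty ablation). Least squares
certifies achievability independently. The lossy-autoencoder ablation
emulates reconstruction error directly — encoder = identity plus
$N(0, 0.5^2)$ noise, decoder = identity — so legacy pairs carry exactly
the label inconsistency reacquisition removes.

# Numerical choices and limitations

* Log-variance clamping at $\pm 10$; KL and CE computed with stabilized
  softmax/log; non-finite losses abort training with the component named.
* All randomness is seeded through one mechanism that restores the
  caller's RNG state; a single pipeline seed fans out to per-stage seeds
  via a fixed affine map.
* Checkpoints are single-file JSON (type-preserving serialization) —
  text-only, diff-able, and round-trip tested bitwise.
* The optimizer is plain gradient descent; no line search or momentum.
  On very anisotropic surrogates more steps may be needed than the
  default 500.
* Stereochemistry, charges, radicals and elements beyond C/N/O/F are out
  of scope; the interpretability gate rejects them rather than guessing.
* Wall-clock latency is not an evaluation surface here; it is
  hardware-bound and the desk-scale oracle would make any comparison
  meaningless.
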