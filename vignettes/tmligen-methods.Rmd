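---
title: "Generative inverse design of transition-metal ligands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative inverse design of transition-metal ligands: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most molecular generative models target organic drug-like chemistry and have
no way to say *how a molecule binds a metal*.  For transition-metal
chemistry that information — which atoms coordinate, with what formal bond
order, and whether the ligand is mono- or bidentate — is the whole point:
two ligands with the same skeleton but different anchor atoms are different
ligands.  `tmligen` implements a complete inverse-design toolkit for neutral
κ¹ (monodentate) and κ² (bidentate) ligands: a string grammar that makes
metal coordination part of the molecule, a junction-tree variational
autoencoder (JT-VAE) that learns and samples ligands in that grammar,
quality metrics for generated sets, ligand property descriptors, and
directional latent-space optimization against one or two target properties.

# The metal-anchored SMILES grammar

The coordination mode is serialized with placeholder atoms chosen from
elements absent from organic ligand chemistry, so they can never collide
with genuine ligand atoms:

| coordination mode                | encoding                         |
|----------------------------------|----------------------------------|
| κ¹, formal bond order 1          | `L->[Li]` (dative bond)          |
| κ¹, formal bond order 2 (carbene)| `L=[Be]` (formal double bond)    |
| κ², orders (1,1)                 | metallacycle `L->[Ir]<-L'`       |
| κ², one order-2 anchor           | `L=[Be]->[Ir]<-L'`               |
| κ², two order-2 anchors          | `L=[Be]->[Ir]<-[Be]=L'`          |

Dative bonds are written with the ASCII tokens `->` / `<-`; the typographic
arrows `→` / `←` are accepted on input.  `[Li]` works because lithium is
monovalent under SMILES valence rules, `[Be]` because beryllium is
divalent, and `[Ir]` because iridium tolerates the higher valence a
chelate needs.  The placeholders carry no metal identity: a decoded anchor
set can be handed to any transition metal.

Two modeling details deserve a note:

* **Carbenes.**  A free divalent carbene written `[CH2]` becomes a normal
  tetravalent carbon once `=[Be]` is attached.  Decoding reverses this by
  freezing the anchor's hydrogen count *before* stripping the placeholder
  (the divalent resonance form), so no pentavalent carbon can appear in a
  decoded ligand.
* **η² (haptic) coordination.**  Adjacent κ² anchors are legal only when
  they share a multiple bond whose π electrons provide the donation;
  ethylene bound side-on encodes as `C1->[Ir]<-C1`, the π bond traded for
  the two dative bonds of the metallacyclopropane form.  The codec
  round-trips these, but the training filters exclude them: generation is
  defined over dentate ligands with nonadjacent anchors.

Canonicalization operates on the anchored string: atoms are ranked by
iterative invariant refinement (element, degree, charge, hydrogen count and
incident bond codes, then neighbor-rank multisets until the partition is
stable) and remaining ties are split one class at a time followed by
re-refinement.  Atoms still tied after refinement are treated as
symmetry-equivalent; this assumption holds for the ligand chemistry the
package generates (it would fail only on refinement-resistant regular
graphs, which do not occur here).  The writer's traversal is fully
determined by the ranks, so any atom-order permutation of one ligand maps
to one string, and `canonicalize()` is idempotent.

The package speaks a Kekulé-only SMILES dialect: aromatic (lowercase)
input is rejected with an explicit message rather than silently
mis-parsed, and all output is kekulized.

# Corpus and the fixture generator

Training corpora are lists of records (id, anchored SMILES, decoded
ligand).  The training filters keep neutral ligands with at least 4 heavy
atoms (placeholders excluded), matching denticity, nonadjacent κ² anchors,
and drop ligands containing *high-valent anionic atoms* — an atom with
negative formal charge whose explicit valence exceeds its element's lowest
standard valence (the classic upstream artifact being anionic pentavalent
phosphorus).  Every rejection is tallied by reason, and kept + rejected
always equals the input count.

The fixture generator defines the package's study conditions when no
external library is used.  It enumerates scaffold families typical of
experimentally derived ligand sets — pyridines, amines, phosphines,
imines, acyclic diaminocarbenes, ketone/thioketone O/S donors, nitriles
and phosphites for κ¹; ethylenediamine-, diphosphine-, amino-phosphine-,
diimine- and carbene-amine chelates for κ² — crossed with the substituent
set {H, Me, F, CF₃, OMe, Ph, NH₂, iPr}, restricted to H/C/N/O/F/P/S/Cl.
Instantiated templates are decoded through the codec, filtered, and
deduplicated on canonical strings, giving roughly 300 distinct ligands per
mode; `n` records are then drawn without replacement under a fixed seed,
with mixed mode stratified to a ~1:1 κ¹:κ² ratio.  What the fixtures do
**not** emulate: fused polycyclic ring systems, the heavy-tailed size
distribution of database ligands (fixtures are small, ~5–20 heavy atoms
versus ~35 atoms per ligand in curated libraries), elements beyond the
list above, and assignment noise.  Tests passing on fixtures therefore
certify the machinery, not performance on real libraries.

# The generative model

The JT-VAE follows the junction-tree idea: a molecule is coarse-grained
into clusters — simple rings (rings sharing ≥ 3 atoms merged, which
collapses bridged systems), bonds outside rings, and singleton atoms
wherever an atom belongs to ≥ 3 clusters — connected into a maximum
spanning tree over shared-atom counts with label-based deterministic
tie-breaks.  Placeholder atoms and dative bonds sit inside clusters like
any other atom or bond; that is precisely what makes coordination
learnable.  The tree is rooted at the cluster holding the
highest-priority placeholder (Ir > Li > Be), so every serialization
starts at the metal anchor.

The tree is serialized as a DFS token stream: a root token, child tokens
`D|<fragment>|<parent slots>|<child slots>` that name the attachment atoms
on both sides, an ascent token, and an end token.  This stream is lossless:
assembling it fragment-by-fragment reproduces the molecule exactly, which
the tests verify on every fixture.

Given the absence of a deep-learning runtime in the target environment,
the encoder/decoder are implemented directly over matrix algebra with
hand-written backpropagation and Adam:

* **Encoder** — linear Gaussian heads on two feature blocks: token counts
  (tree block → z_tree, 28 dims) and composition/bond/ring counts plus a
  64-bit folded circular fingerprint (graph block → z_graph, 28 dims).
* **Decoder** — a recurrent network over the token stream,
  `h_t = tanh(W_x e_{t-1} + W_z z + W_h h_{t-1} + b)`, with the latent
  point injected at every step and a softmax over the token inventory.
* **Loss** — teacher-forced cross-entropy + KL(q(z|x) ‖ N(0, I)) with a
  linear KL warm-up, plus a weighted mean-squared property loss when a
  property head is attached (a one-hidden-layer MLP on z, differentiable
  in closed form).

Decoding enforces chemical validity *by construction*: at each step the
token softmax is masked to structurally legal moves (root only first;
ascent/end only at legal depths; attachment only when the parent slot
exists and matches the child's element and charge), and the sampled token
is applied through the actual assembly step, which also checks valence;
an infeasible choice is excluded and redrawn.  Draws whose decoding
dead-ends are resampled and counted.  Anchor-pattern validity is *not*
forced — it is measured downstream, which is what makes the reported
validity percentages meaningful.

Defaults (hidden 64, embedding 24, latent 28 + 28, 120 epochs, Adam
5 × 10⁻³, KL weight 0.005 with 20-epoch warm-up) were chosen once as the
smallest configuration that overfits a few-hundred-ligand corpus cleanly;
all are exposed in `jtvae_config()`.  Sampling uses softmax draws at
temperature 1 from standard-normal latents; reconstruction uses the latent
mean and greedy decoding with the same mask.  Separate κ¹, κ² and joint
(mixed-corpus) trainings mirror the three generation tasks.

# Quality metrics

The funnel is fixed: validity (anchor-pattern check for the declared mode)
→ uniqueness among the valid → novelty of the unique against the training
set, all on canonical anchored strings, so a skeleton bound through two
different atoms counts as two ligands.  Diversity follows the cited metric
suite's conventions, documented here because they differ: the average
Tanimoto coefficient is taken over unordered distinct pairs, while IntDiv2
is `1 − sqrt(mean TC²)` over ordered pairs *including* self-pairs (hence
`1 − sqrt(0.5)` for a disjoint pair).  Fingerprints are radius-2 circular,
2048 bits, computed on free ligands; all similarity thresholds in the
package are defined relative to this specification.

The synthetic-accessibility score follows the fragment-contribution idea:
common atom environments lower the raw 1–10 score, ring complexity
(fusions, macrocycles) and size raise it, and the normalized score is
`(10 − s)/9` so 1 means easiest to synthesize.  Because the original
PubChem-derived fragment table is not redistributable, the fragment
frequencies come from the package's own fixture enumeration; absolute
values are therefore not comparable with PubChem-based scores, while
orderings (ethane easier than a fused polycycle) are stable and tested.
log P is a Crippen-style atom-contribution sum over a reduced,
package-defined type table; it is a pure function of the graph.

# The steric-bulk descriptor Bk_M

Bk_M quantifies crowding where the metal would sit.  For each anchor, a
probe sphere (radius 3.5 Å) is centered 2.0 Å from the anchor along its
vacant coordination vector (opposite the mean of unit vectors to its
neighbors; a perpendicular fallback handles linear anchors), and Bk_M sums
over ligand atoms (anchor excluded) the overlap volume between each atom's
Bondi van-der-Waals sphere and the probe, by grid integration at 0.2 Å
spacing.  κ² ligands sum both probes, so chelates accumulate roughly twice
the bulk of comparable monodentates.  A Monte-Carlo rejection-sampling
integrator over the same geometry serves as an independent cross-check
(agreement within 2% is an acceptance requirement).  The probe geometry is
a package definition exposed as a config block (`bk_m_config()`), so an
alternative probe construction can be swapped in without touching callers.
Conformers come from a seeded distance-geometry embedding run as a batched
external service; one seed gives one conformer, so the descriptor is
deterministic per seed.  Using a single conformer rather than an ensemble
is a deliberate trade of conformational averaging for reproducibility.

# Conditional generation and optimization

Labeling attaches two named properties to each record — computed
internally (log P, Bk_M) for the self-contained path, or supplied as an
external table for quantities like a complex's HOMO–LUMO gap and metal
partial charge, which this package deliberately does not compute.
A hand-rolled isolation forest (100 trees, subsample 256, random
axis-aligned splits, path-length scores normalized by the standard c(n)
term) removes the `floor(contamination · n)` most anomalous records in
property space before conditional training.

Prompts are drawn from property-space regions: R1/R2 the top decile of
y₁/y₂, R3/R4 the bottom decile, and C the center (both properties within
0.5 standard deviations of their means).  The deciles and the 0.5-sd
center are package thresholds for regions that are usually drawn by eye on
a scatter plot.  The eight compass directions are the four axis-aligned
single objectives (±y₁, ±y₂) and the four equal-weight diagonals scaled
1/√2, in normalized property space.

Optimization is plain gradient ascent with backtracking on
`g(z) = d · ŷ_norm(z)`: initial step 0.1 latent units along the
normalized gradient, decode the candidate, compute the Tanimoto similarity
of its free ligand to the prompt, and reject the step (halving the step
size, up to 6 retries) if similarity falls below the threshold or the
predicted objective does not improve.  Termination: objective improvement
below 10⁻⁴, the step budget (80), or similarity exhaustion.  Step 0 of
every trajectory is the encoded prompt; the accepted-step predicted
objective is non-decreasing by construction.  Because the decoder is
piecewise constant over latent space, consecutive accepted moves often
decode to the same ligand; the trajectory records a step only when the
decoded molecule changes, so its length counts distinct intermediate
ligands, and a trajectory of length 1 means the optimizer never produced
a new similar ligand (the "not similar" outcome of the funnel).  All
funnel percentages use conditional denominators in that order —
verification is assessed only on the similar, valid, unique and novel
outcomes.  Verification is
strict and zero-tolerance: the oracle-computed change must have the
requested sign for *every* property with a nonzero direction component,
and ties count as unverified — for diagonal directions both properties
must move.  Because the similarity gate acts on decoded free ligands,
anchors do not contribute to the similarity; this is a documented choice.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run everything at desk scale,
chosen once as the package's study conditions: fixture corpora of 230–250
ligands per mode, 150-epoch trainings, 1000-draw unconditional samples,
and a 5-prompt × 8-direction conditional campaign with center-region
prompts, a 0.20 similarity threshold and a 0.35 Å labeling grid for Bk_M.
Degenerate inputs fail loudly rather than silently: empty corpora,
degenerate property variance, empty regions, contamination outside (0,
0.1], and fingerprintless similarity all raise (or, for the two-empty-
fingerprint case, return 0 with a warning).  Assembly tie-breaks are by
logit order with canonical-string order as the final tie-break, so
decoding is deterministic given z.

# Known limitations

* The canonicalizer's equivalence assumption (post-refinement ties are
  automorphic) is safe for this chemistry but unproven in general.
* The SA score's fragment table is corpus-derived, not PubChem-derived;
  only orderings should be interpreted.
* log P uses a reduced atom typing; absolute values are approximate.
* The Bk_M probe definition is a package construction; its absolute scale
  is not comparable to other buried-volume-style descriptors.
* Charged ligands, polynuclear complexes and haptic-ligand *generation*
  are out of scope (haptic encoding is supported by the codec only).
* The generative model is a latent-conditioned recurrent decoder over
  junction-tree tokens, sized for hundreds of training ligands; scaling to
  tens of thousands of ligands would warrant message-passing encoders and
  minibatched training, which the config structure anticipates but the
  implementation does not prioritize.
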