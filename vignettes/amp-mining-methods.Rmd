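---
title: "Mining digestion-survivable antimicrobial peptides: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining digestion-survivable antimicrobial peptides: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampsieve)
```

## The model

`ampsieve` asks a compound question of every protein in a proteome set:
does it contain an antimicrobial region, would gastric digestion release
that region as a peptide, and would the released peptide persist in the
intestine? Each clause is a separate, independently testable model.

### Antimicrobial propensity scan

Antimicrobial character is modelled as a per-residue propensity (strictly
positive, dimensionless; *lower* = more antimicrobial, because the scale
derives from inhibitory-concentration measurements where potent residues
score low). A window of `window = 7` residues slides along the protein
and the window mean is compared with `threshold = 0.225` (strict `<`,
following the "below the threshold" convention). A maximal run of
consecutive qualifying window starts $w_1 \dots w_k$ is reported as the
stretch $[w_1,\; w_k + W - 1]$ — every residue of the span belongs to at
least one qualifying window. Spans shorter than `min_stretch = 12`
residues are discarded; observed stretches in practice top out in the
low 40s, which motivates the fragment length cap below.

Two conventions were genuinely open and are fixed here:

* **Stretch propensity (PV)** is the mean *residue* propensity over the
  span, not the mean of window means. It is single-valued and
  reconstructible from the table output.
* **Adjacent runs are not merged.** Two maximal runs separated by a
  single failing window can produce spans that overlap by up to
  `window - 2` residues; both are reported, in position order. Merging
  would hide the failing window and make the construction
  non-idempotent under threshold changes.

Windows that touch an ambiguity letter (B, J, O, U, X, Z) are omitted —
the scale does not define them — and such letters also break runs.
Records containing them are flagged on input, never silently altered.

### Digestion model

Cleavage specificity is a data table, not code: each row constrains the
residues at P4…P4′ around a candidate bond (Schechter–Berger numbering),
and a bond is cleaved when some `pattern` row matches and no `exception`
row matches. Context positions beyond a terminus satisfy only conditions
that do not require a residue (so a negated set `^P` passes, a positive
set fails). Bonds whose P1 or P1′ residue is an ambiguity letter are
never called: the rules are undefined there, and not cleaving is the
conservative choice for a stability score.

Gastric release is modelled as **complete-and-partial pepsin digestion**.
With $N_{Pa}$ pepsin (pH < 1.8) sites, the $N_{Pa} + 2$ boundaries
(termini included) define

$$C_s = \binom{N_{Pa} + 2}{2} - 1$$

candidate peptides — every boundary pair except the intact protein.
This one enumeration covers every fragment obtainable under *any* subset
of hydrolysed sites (verified against a brute-force subset oracle in the
tests). Fragments are kept at 12–47 residues inclusive: 12 is the
minimum stretch length, and 47 is the longest stretch the scan is
expected to produce (43) plus the two-residue matching margin at each
terminus.

A fragment *matches* a stretch when it comes from the same parent,
contains the stretch completely, and overhangs it by at most
`max_overhang = 2` residues on either side; zero overhang on both sides
is an *exact* match. Because matching is coordinate-based within one
parent, sequence identity over the overlap is automatic. Matches are
**deduplicated by peptide sequence before scoring** (one score per
reportable peptide); the representative stretch is the lowest-PV
witness, the most conservative antimicrobial call. All witnesses are
retained for back-tracing.

### The protease rule dialect

The shipped tables encode trypsin with its full pattern-plus-exception
set (proline veto, the WK↓P and MR↓P overrides, and the Keil
exceptions), enterokinase as an acidic triplet before the lysine,
thrombin with both its narrow and extended contexts, chymotrypsin in
low- and high-specificity variants, and pepsin as a simple bidirectional
rule — a bond is cleavable when either P1 or P1′ carries a pepsin target
residue (F/L below pH 1.8; F/L/W/Y above pH 2).

Two dialect choices could not be settled from first principles: the
chymotrypsin variant, and whether pepsin carries additional positional
vetoes. Both were **calibrated against a single benchmark stability
computation** (the peptide FHKFICKMMKIYL, whose intestinal-panel site
count must total 14, giving CSS = 6.67): the low-specificity
chymotrypsin variant together with the simple bidirectional pepsin rule
is the unique combination among the candidate dialects that reproduces
it, so those are the defaults. The high-specificity chymotrypsin variant
remains available (`cleavage_rules(chymotrypsin = "high")`), and because
the tables are data files, any rule correction is an edit, not a code
change.

### Stability and ranking

Released peptides are scored **in isolation** — their termini are true
termini for context purposes — because the object of interest is the
free peptide after gastric release, not the bond in its parent context.
The cleavage stability score is

$$\mathrm{CSS}_x = \frac{100}{1 + \sum_i N_x^i}, \qquad
  i \in \{Pb, CT, E, T, Th\},$$

and persistence is summarised by the first-order decay rate
$d_x = \ln 2 / \tau_x$ with the half-life $\tau_x$ in seconds. Half-life
*prediction* is out of scope: the provider interface accepts a lookup
table (e.g. batch output of an external predictor) or a deterministic
stub ($\tau = 1$ s) that is flagged `"stub"` in every output row —
honesty over imitation. With a constant stub, decay contributes nothing
to the ranking and CAS reduces to stability over propensity.

The combined antimicrobial score normalises each variable by its maximum
over the full pooled peptide set of the run and forms

$$\mathrm{CAS}_x =
  \frac{\overline{\mathrm{CSS}}_x}{\overline{PV}_x \cdot \bar d_x}.$$

Pooled (not per-proteome) normalisation keeps one common ranking from
which per-proteome metrics are derived. CAS is invariant to rescaling
any one input column (the normalisation absorbs it) — a property the
test suite asserts — and it deliberately lets a peptide with the best
propensity rank poorly if its decay is fast. All three inputs must be
strictly positive; violations abort with the offending peptides listed
rather than being clamped, since CAS divides by two of them. Ties break
by higher CSS, then lexicographic peptide sequence, making ranks a
deterministic permutation. The default report keeps the top 100
peptides; the cutoff sizes the subset and carries no scoring meaning.

### Physicochemical descriptors

Net charge is a Henderson–Hasselbalch sum over termini and ionizable
side chains (EMBOSS-style pK table), the isoelectric point its bisection
root on pH ∈ [0, 14] to 1e-4 (a charge curve with no sign change returns
the nearer boundary with a warning), hydrophobicity the Eisenberg
consensus scale mean, and the amphipathicity index the normalised
hydrophobic moment at 100°/residue — the standard formula-defined proxy
for helical amphipathicity; external predictors compute related but
undocumented indices, so exact agreement with them is a non-goal. All
three resource tables (pK, hydrophobicity, masses) are editable data
files; molecular weight offers average (default) and monoisotopic
masses.

## The synthetic generator

`simulate_proteomes()` emulates what the pipeline needs from real data:
proteome sets of a few hundred proteins, log-normal lengths
(`meanlog = log(250)`, `sdlog = 0.45`, the scale of whey protein
sequences), about one planted antimicrobial stretch per protein
(`plant_rate = 1`, Poisson), plant lengths uniform on [12, 43], and
whole-protein copying between sets (`share_prob = 0.15`) to create the
cross-proteome overlap structure that the set-analysis functions
summarise. Six sets named like the motivating milk/cheese collections
are the default.

The construction makes recall assertions *exact* rather than
statistical:

* plant edges use residues whose propensity sits just below the
  threshold (M, with F at a terminus when a pepsin site is wanted
  there), and flank zones are filled with D/E, far above it — so every
  window straddling a plant boundary fails and the called stretch
  coincides with the plant exactly;
* the pepsin trigger is an F at the plant terminus (`overhang_mode =
  "exact"`), or an L placed in the flank at the offset that realises the
  sampled 1–2-residue overhang (`"jitter"`), or 3 residues out
  (`"reject"`, which leaves no admissible match at all — cleavage on
  both sides of an L is accounted for in the offsets);
* background is drawn only from residues comfortably above the
  threshold, and every generated protein is verified by running the real
  scan — a clash resamples the background, so specificity holds by
  construction, not on average.

What the generator does **not** emulate: homology to real milk protein
families, realistic residue composition outside the plants, correlated
cleavage-site density, or any relationship between a peptide's sequence
and its half-life (synthetic τ are i.i.d. log-normal, `meanlog = -0.5`,
`sdlog = 1`, centring decay near 1/s). Passing the planted-recovery
tests therefore demonstrates the pipeline's bookkeeping — coordinates,
enumeration, matching margins — not predictive accuracy on real
proteomes, which is bounded by the propensity scale and the rule tables.

## Numerical and testing choices

Everything is deterministic: there is no randomness outside the
generator, which is seeded, and pipeline reruns are byte-identical
(timings are deliberately kept out of the manifest). Tests compare the
scan against a naive window-enumeration oracle (1,000 random 60-mers),
the fragment enumeration against the closed form and a subset oracle
(200 random proteins of 20–500 residues), the ranking against an
unnormalised-ratio oracle (200 peptides), and the planted-recovery
design at 5 sets × 100 proteins — sizes chosen to exercise the
combinatorics well past any edge case while keeping the default test run
fast. Property tests use synthetic two-valued scales so that scan
correctness is independent of the shipped scale's provenance; the
shipped per-residue values are a transcription of the published
propensity scale and are editable without touching code.

Degenerate inputs are defined, not accidental: sequences shorter than
the window give an empty profile; a protein with no pepsin site yields
zero fragments (the intact chain is never a digestion product); an empty
match set ranks to an empty table; a singleton ranking has all
normalised bars equal to 1 and CAS = 1.

## Limitations

* The propensity scan is scale-driven; it inherits whatever biases the
  chosen scale has, and the shipped default is a transcription, not a
  fit.
* No cleavage kinetics: a site either exists or not, and partial
  digestion is modelled combinatorially, not dynamically.
* Half-lives are external inputs; the stub is a placeholder that
  neutralises the decay term, not an estimate.
* Microbial proteases are deliberately omitted from the intestinal
  panel, and membrane-penetration screening is an optional external
  annotation, not a built-in predictor.
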