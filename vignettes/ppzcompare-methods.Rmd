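---
title: "Methods: grouped-alignment conservation classes and BS3 cross-link identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grouped-alignment conservation classes and BS3 cross-link identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures behind `ppzcompare`, the
assumptions they make, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
underlying procedure was verbal rather than numeric.

## 1. The comparative conservation model

### Input and containers

The unit of analysis is a *joint* multiple sequence alignment of two
paralogous ortholog groups — PP1-type and PPZ-type phosphatase catalytic
domains — with a per-sequence group label (`PP1`/`PPZ`) and a clade label.
The alignment itself is an input: `ppzcompare` deliberately does not compute
MSAs (that is an upstream aligner's job), but it does provide a pairwise
global aligner for reference-to-reference position transfer. Because PPZ
proteins carry a long N-terminal extension absent from PP1, the PPZ
sequences are expected to be trimmed to their catalytic domain before
alignment; `trim_to_domain()` does this while preserving full-length
numbering through the record's `offset` (the default domain start used in
the examples is residue 359 of the 692-residue budding-yeast PPZ). Every
position the package reports is a 1-based full-length residue number; the
spectroscopy arm and the contact map follow the same convention.

### Column profiles

For each column and group we compute: residue frequencies over non-gap
entries, the gap fraction, the dominant residue and its frequency, the
cumulative frequency of the dominant residue's conservative-substitution
group, and the frequency of each charge category. Ties for the dominant
residue are broken alphabetically so all outputs are deterministic.

### Thresholds behind the verbal categories

The source procedure is described in words — "invariant or largely
maintained", "virtually constant", "substantial variation", "quite
constant". Words are not thresholds, so the package fixes defaults and makes
every one of them configurable (`conservation_config()`):

| parameter | default | meaning |
|---|---|---|
| `theta_cons` | 0.90 | dominant frequency for constant/maintained |
| `theta_var` | 0.70 | dominant frequency *below* which a column is variable |
| `allow_simgroup` | TRUE | conservative-substitution groups may satisfy `theta_cons` |
| `max_gap_conserved` | 0.0 | gap tolerance for "conserved" (present in all sequences) |
| `max_gap_class` | 0.1 | gap tolerance during A–D classification |
| `theta_charge` | 0.90 | modal charge-category frequency for "quite constant" |

The gap between `theta_var` and `theta_cons` is intentional: columns whose
dominant frequency falls in `[0.70, 0.90)` are neither constant nor
variable, which keeps the B/C classes from absorbing mildly noisy columns.

Conservative-substitution groups default to a Boxshade-style partition
({AVLIM}, {FWY}, {ST}, {NQ}, {DE}, {KR}, {H}, {C}, {G}, {P}); the exact
scheme used by the original shading tool is not published, so the partition
is a config value. Charge categories default to acidic = {D,E},
basic = {K,R}, everything else neutral; histidine is neutral by default
(side-chain pKa ≈ 6) and can be declared basic — the headline K↔D swaps are
insensitive to this choice.

### The same-similarity-group rule

One classification subtlety is deliberate. A column where both groups pass
`theta_cons` *only via the similarity group*, with two dominants from the
*same* group (say T versus S), is not called a difference: with conservative
background substitution this pattern arises from sampling noise inside one
group of interchangeable residues. The difference is believed only when the
two dominants are residue-level constant on both sides (the conserved
V-versus-I case) or come from different similarity groups. Without this
rule, synthetic benchmarks show honest-looking but spurious class A/D calls
at exactly the rate binomial sampling predicts.

### Class D and clades

Class D (clade-restricted difference) is evaluated against per-clade
profiles; a clade participates only when it retains at least
`min_clade_seqs` (default 3) sequences per group, because dominant
frequencies over one or two sequences are meaningless. Precedence is
A > B > C > D, so a column classed globally is never also reported as
clade-restricted.

### Identity, divergence and the phylogram

Pairwise identity is matches over mutually non-gap columns. The
neighbor-joining implementation is the standard agglomerative algorithm on
`1 − identity`, written in-package for two reproducibility guarantees the
usual library routines do not make: Q-criterion ties are broken by the
lexicographically smallest pair of cluster labels, and negative branch
lengths are clamped to zero with the deficit shifted onto the sister branch,
so the emitted newick is bit-reproducible. With three or more taxa the tree
is written unrooted with a trifurcating root; with two, the distance is
split evenly. Correctness is checked in the tests against the three-taxon
closed form and an exhaustive split oracle on additive quartets (with the
`ape` parser as an independent reader).

### Logos

Information content uses the 20-letter alphabet maximum `log2(20)` with
frequencies over non-gap entries only. Gap-only columns get IC 0. An option
(`scale_by_gaps`, off by default) multiplies IC by the non-gap fraction;
the exact gap treatment of the web logo tool the field uses is not
published, so the default is the plain non-gap convention and the scaling is
opt-in.

## 2. The cross-link identification model

### Filter

A scan survives when (i) its precursor charge is within `[3, 9]` —
cross-linked species concentrate at high charge, and +2 scans are almost
always linear peptides; (ii) it contains at least one peak within 0.10 Da of
a tryptic y1 signature ion (y1 of K, 147.113; y1 of R, 175.119 — either
suffices, since requiring both would discard every peptide pair ending in
the same residue type); and (iii) at least one configured cross-linker
signature peak. The upstream tool's linker-signature list is proprietary and
unpublished, so the package default — y1 of K carrying a BS3-water or
BS3-ammonia dead-end — is an explicit package choice, declared in config and
asserted nowhere as a constant.

### Chemistry as formulas

Every mass constant is computed at load time from elemental monoisotopic
masses: BS3 bridge C8H10O2 (138.0681), dead-ends C8H12O3 / C8H13NO2,
carbamidomethyl C2H3NO (fixed on every Cys), oxidation O (variable on Met,
at most 2 per candidate by default). Nothing is typed as a decimal twice,
so the mass-additivity invariant (`m(pair) = m(A) + m(B) + bridge`) is exact
by construction and the tests can demand 0 ppm on constructed spectra.

### Digestion and link-site legality

Trypsin cleaves C-terminal to K/R, not before P (toggleable); all peptides
with up to 4 missed cleavages are enumerated. A lysine can carry the link
only if it was *not* cleaved, so the C-terminal K of a peptide is not a
legal site — unless the peptide ends the protein. The protein N-terminus
(position 1) is a legal site regardless of residue, because the
alpha-amine is reactive. Four missed cleavages are necessary, not generous:
every linked or dead-end K blocks one cleavage by construction.

### Candidates, fragments, approval

For each retained scan, the neutral precursor mass is
`m/z × z − z × m(proton)`. Peptide pairs within 10 ppm (after accounting
for the bridge and any oxidations) are expanded over all legal site
combinations; single-peptide dead-end (BS3-water, BS3-ammonia) and plain
linear explanations are enumerated alongside. Met-oxidation *positions* are
enumerated explicitly (bounded by the config cap) rather than treated as a
mass-only correction, so fragment masses stay exact. Theoretical b/y ions
run over ordinals 1..n−1 at fragment charges 1–2 (higher fragment charges
explode the candidate space at desk scale and are configurable); ions
spanning the linked residue carry the partner peptide plus bridge. A
candidate is approved iff **each** peptide has at least one matched b/y ion
(`min_ions_per_peptide`, default 1) — the published validation rule.
Scoring is the matched-ion count with ties broken by absolute ppm error and
then lexicographically; there is deliberately no decoy/FDR machinery,
because the modeled workflow validates by the both-peptides rule plus
manual inspection, and intensity is ignored since the rule is
presence-based.

## 3. The contact map

Cross-link records store *sets* of sites per side: the published tables
cannot always distinguish neighboring lysines (e.g. a 356/359 pair), and
the package never resolves that ambiguity by choice. Counting is
fractional — a record spreads weight 1/(|sitesA| × |sitesB|) over member
pairs, so totals are conserved — while edge exports are exhaustive, one
flagged edge per member. Region schemes (e.g. N-terminal extension versus
thirds of the conserved domain) are half-open interval lists supplied by
the user, since the domain boundaries are not published constants. A config
offset converts construct numbering (e.g. a Δ1–344 expression construct) to
full-length coordinates on ingest.

## 4. What the generators emulate — and what they do not

### Ortholog families

`simulate_family()` draws a uniform ancestral sequence and evolves each
species copy independently at the clade's per-site substitution probability
(default 0.05, conservative moves within the similarity group by default),
over a star-of-stars clade structure shaped like the analyzed data set
(five clades, six species per group each). Planted columns are forced to
their class pattern and carry no noise; class B/C variable sides cycle
through eight residues drawn from eight different similarity groups, which
bounds the dominant frequency near 1/8 and keeps the planted class
unambiguous at any group size.

Two deliberate simplifications:

* **No shared clade-branch substitutions by default** (`clade_divergence = 0`).
  A substitution on a clade root is inherited by the whole clade and can
  produce a genuine — but unplanted — clade-restricted difference. At
  realistic rates this happens at a few columns per thousand, which is
  biologically fine but fatal for a ground-truthed benchmark whose
  acceptance criterion is precision = recall = 1.0 against the planted
  truth. The knob exists for users who want phylogenetic autocorrelation
  and accept that the truth table then undercounts.
* **No indels.** The alignment is correct by construction. Real MSAs carry
  alignment error, so a green planted-recovery test establishes that the
  classifier implements its definition, not that it is robust to
  misalignment.

There is no rate heterogeneity and no empirical exchange matrix; the
generator is a bookkeeping device for planted truth, not a phylogenetic
likelihood model.

### Spectra

`simulate_xlms()` picks, for each requested link, the smallest legal
tryptic peptide pair covering the sites, emits the full b/y series of both
peptides (with cross-link arithmetic) at charges 1–2, the configured
signature peaks, optional uniform noise peaks and charge-2 decoy scans.
Precursors are exact (0 ppm) unless Gaussian ppm jitter is requested.
Intensities are uniform random — the search ignores them by design. No
isotope envelopes, no retention time, no co-elution chimeras: recovery
tests prove the search implements its rules, not that it would survive a
real instrument's artifacts.

### Synthetic reference stand-ins

The coordinate anchors quoted in the literature (a PP1 K210/K259 opposite
PPZ D566/D615, an RVxF-like motif at 263 of the 562-residue inhibitor, a
692-residue PPZ) refer to database sequences that an offline build cannot
fetch. `synthetic_reference_proteins()` constructs stand-ins that reproduce
the *geometry* by construction: a 312-residue PP1-like protein, a
692-residue PPZ-like protein whose residues 359..668 are a conservatively
mutated copy of PP1 residues 3..312 (so PP1 position p sits at PPZ position
356 + p), and a 562-residue inhibitor with the motif planted at 263 and
lysines at the published cross-link positions. Tests against these verify
the *machinery* — alignment-based position transfer, motif scanning,
digestion — not the biological sequences, and every such object is labelled
synthetic.

## 5. Numerical choices and degenerate inputs

* Isoelectric points use Henderson–Hasselbalch bisection on pH ∈ [0, 14] to
  1e-4, with a Bjellqvist-style pKa table in config; agreement with any
  specific web calculator is not asserted.
* `X` residues: mass and pI computations reject them (silent approximation
  would corrupt masses); counting treats them as non-Ser/Thr; profiles
  exclude them like gaps.
* Trailing `*` stop characters are stripped on FASTA input; internal `*` is
  an error naming record and position.
* MGF blocks without CHARGE are skipped with a warning (dialects vary and
  the filter would discard unknown charges anyway); a block without PEPMASS
  is an error.
* All-gap columns profile as "no dominant residue" and never classify.
* Scans surviving no filter produce a warning and empty-but-valid outputs,
  never an error.
* Pipeline reports are TSV with `#` provenance headers (package version,
  config hash, seed) and no timestamps, so reruns are byte-identical.

## 6. Dependency choices

FASTA parsing and global alignment (Needleman–Wunsch, affine, BLOSUM62,
gap open 10 / extend 0.5) are delegated to Biostrings; alignment scores are
verified in the tests against an exhaustive dynamic-programming oracle on
tiny instances. The MGF reader is written in-package because no MGF parser
is available in the dependency set. Neighbor joining is written in-package
for the determinism guarantees described above, with `ape` used in tests as
an independent oracle only. Configuration files are JSON (via jsonlite)
rather than YAML, which has no parser in the dependency set; all pipeline
functions equally accept plain R lists.

## 7. Known limitations

* The published headline counts (141/50 conserved positions, 26/27/3/5
  class sizes, 30 charge changes) are not reproducible without the original
  131 sequences and the unstated thresholds; the package's acceptance is
  therefore property-based on planted-truth synthetics, and the numeric
  thresholds here are declared defaults, not recovered constants.
* Class D detection requires labeled clades with enough members; sparse
  clades silently drop out of the per-clade profile set.
* Fragment matching is presence-based at a flat 0.10 Da; no ppm-scaled MS2
  tolerance, no intensity model, no FDR.
* The contact map is two-dimensional by design; no structural mapping or
  distance-restraint export.
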