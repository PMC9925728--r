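---
title: "Annotating H2O2-scavenging enzyme families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating H2O2-scavenging enzyme families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Catalase (CAT), peroxiredoxin (PRX) and glutathione peroxidase (GPX) are the
three major enzyme families that detoxify hydrogen peroxide in animals, and
sulfiredoxin (SRX) is the ATP-dependent reductant that reactivates
hyperoxidized typical 2-Cys peroxiredoxins. Surveying them across many
predicted proteomes is a filter chain, not a single model: domain
architecture nominates candidates, catalytic-site motifs separate functional
members from degenerate gene models, active-site profiles and tree placement
assign subfamilies, and the result is a per-species census. `antioxscan`
implements that chain as composable, individually tested stages.

```{r, eval = FALSE}
library(antioxscan)
cfg   <- synthetic_config(seed = 1)
paths <- write_dataset(generate_dataset(cfg), "survey")
res   <- run_classify(paths$manifest, paths$domtblout, "survey/out")
res$census
```

# Candidate nomination from domain architecture

Candidates come from a HMMER3 per-domain table (`hmmscan --domtblout`
dialect; `hmmsearch` orientation is auto-detected). Envelope coordinates
define the domain interval — the envelope is the conventional inclusive
extent in per-domain tables — and coordinates are 1-based inclusive
throughout, matching both HMMER convention and residue-numbering practice.

The bundled rules are:

| family | require all            | require any          |
|--------|------------------------|----------------------|
| CAT    | PF00199, PF06628       | —                    |
| PRX    | PF00578                | PF08534, PF10417     |
| GPX    | PF00255                | —                    |
| SRX    | PF02195                | —                    |

Two points are deliberately configurable rather than hard-coded. First, the
per-domain independent e-value threshold defaults to 1e-5 — a conservative,
widely used cut-off; published counts obtained with other settings can be
chased by changing `classify_config(max_evalue =)`. Second, the PRX
accessory-domain requirement can be relaxed to optional
(`prx_any_optional = TRUE`): PF08534 and PF00578 naming conventions differ
between sources, so the rule set is data, not code. Multiple hits of one
accession count once for presence logic, and tightening the e-value
threshold can only shrink every candidate set (a property the tests
exercise).

# The motif grammar and scanner

The catalytic-site filters need exactly four constructs: fixed residues,
alternations (`[TS]`), a single-position wildcard (`X`) and bounded gaps
(`X{min,max}`). We implement this restricted grammar directly rather than
delegating to a general regular-expression engine, because the scanner's
contract is stricter than a regex match: every start offset is reported
(overlaps included), gaps expand minimally (leftmost gap first) so each
matching start yields exactly one match, and match objects carry the
catalytic-role coordinates downstream stages need. The test suite holds the
scanner equal to an independent regex-based oracle (lazy quantifiers +
lookahead capture) over thousands of random sequences.

Bundled patterns:

* `PXXX[TS]XXC` — the strictly conserved peroxidatic-cysteine (C_P)
  active-site motif; its absence excludes a PRX candidate.
* `F[SG]GCHR` — the SRX N-terminal binding motif required for SRX catalytic
  activity.
* `GGLG`, `YF` — hyperoxidation-sensitivity motifs of AhpC-PRX1, searched in
  the C-terminal half of the sequence by default (both are C-terminal
  motifs in this family; `search = "full"` widens the window).
* `GXSXG` — the lipase/esterase motif of PRX6.
* `HX{0,60}SX{0,60}D` — the phospholipase A2 catalytic triad of PRX6. The
  triad is usually written with unquantified ellipses; we chose 0–60
  residues between consecutive roles as a generous default for a compact
  thioredoxin-fold domain, and expose it (`gap_max`). When a `GXSXG` match
  exists its serine is preferred as the triad serine. A proper subset of
  roles present gives `partial` (with the missing roles listed); all roles
  present but unchainable in order gives `absent`.

Selenocysteine is kept as `U` everywhere and does **not** match `C`-fixed
positions unless the `sec_equivalence` flag is set: whether a catalytic
position holds Sec or Cys is itself a classification output (GPX typing),
not a spelling variant. When several matches of "the" catalytic motif
occur, the leftmost is canonical and the alternatives are counted in the
evidence.

The resolving cysteine (C_R) has no single scannable consensus across
subfamilies, so it is located via subfamily-specific *context patterns*
(conserved flanks with the cysteine slot wildcarded). The AhpC-PRX1 context
is the conserved C-terminal `HGEVCPAGW` region of typical 2-Cys
peroxiredoxins; the PRX5 context and the a/b hyperoxidation-modulating
motif definitions are provisional defaults, clearly marked as such and
supplied as data (`cr_contexts()`, `ab_motif_defs()`) so curated
definitions can be dropped in. A context match with a non-cysteine in the
slot yields `substituted(residue)` — this is how the valine-for-C_R
substitution seen in some sponge PRX5 sequences is reported.

# Family calls

* **CAT** is accepted on architecture alone, with one optional extra: a
  minimum-length floor (default 400 residues). Published CAT surveys
  involve a manual curation step that discards reduced-length catalase
  models after alignment and structural inspection; the floor is an
  explicit, reported approximation of that step, and can be disabled
  (`cat_length_floor = NULL`). Typical catalases run ~500 residues, so 400
  separates full-length models from fragments without clipping genuine
  short variants too aggressively.
* **PRX** is accepted iff the architecture holds *and* C_P is present.
* **GPX** is accepted iff the GSHPx domain is present and the catalytic
  tetrad's first role resolves to Sec or Cys. The tetrad (Sec/Cys, Gln,
  Trp, Asn) is located by globally aligning the query's domain region to a
  bundled reference with annotated tetrad coordinates (BLOSUM62, `U` scored
  as `C`, residues read back from the unmasked query). The bundled
  reference is a *synthetic* construct — adequate for the generator's
  reference-derived sequences and for testing the machinery — and should be
  replaced by a curated GPX reference for production annotation; the
  `reference` argument takes any sequence plus four coordinates. Alignment
  coverage below 60% of the reference gives `undetermined` with a reason.
* **SRX** candidates are recorded but never counted in the census; they
  surface as the species-level tri-state: *competent* (ParBc domain +
  `F[SG]GCHR` in at least one protein), *domain_only*, *absent*.
* A protein nominated by two families is called under the family with the
  higher summed domain bit score, with the conflict logged in its evidence.

# Subfamily classification

**PRX** subfamilies are defined by the active-site sequence. A ±7-residue
window around the C_P cysteine (15 positions) is scored against each
bundled subfamily profile as the mean per-position log-odds against a
uniform 1/20 background, with a 0.01 pseudocount so unseen residues get a
finite penalty. The best label is assigned only if it leads the runner-up
by more than `profile_margin` (default 1.0 on the mean-log-odds scale —
roughly "one consensus position of evidence per window position");
otherwise the call is `unclassified`, and raising the margin can only
convert classified to unclassified, never the reverse. Windows truncated by
a sequence end are scored over the available positions and flagged. The
bundled profiles ship as a plain TSV (`prx_cp_profiles()`) built around the
subfamily consensus windows with the few variable positions given
alternate residues; substitute curated profiles for production use.

**GPX** groups are assigned purely by clade placement — the four
evolutionary groups are a phylogenetic, not a motif, signature — with no
profile fallback; no placement means `unclassified`.

When both a profile call and a clade placement exist for a PRX, the clade
label wins and an agreement flag records whether they coincided: final
subfamily labels follow tree placement, with phylogeny-only refinements of
AhpC-PRX1 (PRX4-like, CNID-PRX-like) folded back into the AhpC-PRX1 census
column.

# Alignment editing, trees, clade assignment

Gap-column editing removes every column whose gap fraction is *strictly*
greater than 0.5 — "more than 50% gaps" keeps the exact-0.50 boundary
column — and reports removed indices 0-based, as alignment editors do. The
filter is idempotent, and a per-column oracle pins its behaviour in the
tests. The editing is per-column; a block-window variant (removing whole
regions) would need a window length that nothing in our inputs determines,
so it is left to configuration of the upstream editor.

Distances are p-distances over mutually ungapped columns (pairwise
deletion), with `U` folded into `C`, optionally Poisson-corrected
(d = −ln(1−p), an error if any pair differs at every compared site). The
pairwise-deletion counting is implemented directly: the available distance
routines either apply complete deletion or count gap-vs-residue columns as
differences, neither of which is the convention we want for ragged
predicted proteomes.

Neighbor-joining (via ape) is the internal, desk-scale tree builder;
negative branch-length artefacts are clamped to zero with the total deficit
recorded. On additive matrices NJ reproduces the generating tree's path
lengths to numerical precision, which the tests verify on random 8-taxon
trees. Supports come from a classical column-resampling bootstrap
(resample alignment columns with replacement, rebuild NJ, count each
reference bipartition), seed-deterministic. Externally built
maximum-likelihood trees (ultrafast-bootstrap newick from IQ-TREE or
similar) are first-class inputs: `run_tree(newick =)` skips NJ entirely,
so the published ML workflow can be mirrored exactly.

Clade assignment treats an unrooted "clade" as a bipartition side: the
smallest side containing the query and at least one labelled reference
leaf. The label is assigned iff all references in that side agree and, when
`min_support` is set, the defining edge's support passes. Causes for
non-assignment (`mixed`, `low_support`, `no_labeled_clade`) are reported.
The implementation is held equal to a brute-force bipartition enumeration
(edge deletion + connected components) across hundreds of random labelled
trees.

# The synthetic data generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, not biological realism. Each planted protein is a uniform-random
scaffold (configurable background frequencies) carrying: synthetic hit rows
for its family's Pfam accessions — domain *presence* is asserted through
the hit table, since profile-HMM search is out of scope and the pipeline's
contract is hit-table-driven — and literally planted motifs at recorded
coordinates. PRX active-site windows are sampled from the bundled
subfamily profiles; GPX bodies are mutated copies of the bundled reference
(6% substitution at non-tetrad positions) so tetrad alignment has
realistic noise; CAT sequences are 450–550 residues (the short-CAT decoy is
300); SRX carries ParBc plus `FSGCHR`.

The default composition per species — 2 CAT, 3 AhpC-PRX1, 1 PRX5, 2 PRX6,
one GPX per evolutionary group, 1 SRX, plus hard negatives (PRX
architecture without C_P, core-domain-only PRX, short CAT, GPX with a
corrupted catalytic slot) and 80 background proteins — yields roughly 100
proteins per species across 19 species, a gene-family complement in the
range reported for metazoan surveys while keeping a full run inside a
couple of minutes.

Lesion types (`cp_knockout` C→S at the catalytic cysteine, `cr_to_val`,
`sec_to_cys`, `gglg_loss`, `yf_loss`, `srx_motif_degradation`,
`truncation`) are applied at configurable rates, recorded in the ledger,
and applied to the base protein *before* duplicates are copied, so
duplicate groups remain exact copies. Because filter motifs can arise by
chance in random scaffolds (a C_P match occurs in roughly 6% of 250-mers,
YF in a quarter of C-terminal halves), candidate sequences are scrubbed:
accidental matches outside planted, surviving motif intervals have one
fixed position mutated until clean. This makes the ledger exact — planted,
unlesioned motifs are found at exactly the recorded coordinates and
nowhere else — which is what lets the funnel tests demand precision =
recall = 1.0 rather than "approximately right".

`generate_subfamily_alignment()` evolves groups from distinct consensus
copies of one root (default: 4 groups × 6 members, 120 columns, 3%
within-group vs 35% root-to-group divergence — far enough apart that group
monophyly and ≥95% bootstrap support are expected outcomes, close enough
that distances stay well away from saturation), and injects gap columns of
recorded fractions for the editing tests.

What passing on synthetic data does *not* show: robustness to real-world
domain-boundary noise, split/fused gene models, alignment error, deep
paralogy, or Sec residues mis-predicted as stop codons. The generator makes
the pipeline's logic falsifiable; it does not certify field accuracy.

# Numerical and procedural choices

* Deduplication groups exact sequence strings within one species and keeps
  the lexicographically smallest id — determinism across platforms. We
  count unique sequence strings per species and report duplicates
  separately, without inferring locus structure (whether variants are
  isoforms of one locus is not decidable from a proteome FASTA).
* Terminal `*` stop characters are stripped on input; internal stops are
  fatal (broken gene models).
* All randomness (generator, bootstrap) is seeded explicitly, RNG state is
  restored afterwards, and the classify/tree outputs are byte-identical
  across reruns with the same inputs and seed — a tested guarantee.
* The audit table lists every input sequence exactly once (accepted,
  rejected with reasons, or duplicate-of), and per-stage funnel logs record
  the counts at each filter, so a census can be traced sequence by
  sequence.
* Problem sizes used by the tests and the acceptance script (19 species ×
  ~100 proteins; 1 000 random 300-mers for the scanner oracle; 50 random
  8-taxon trees; 200 random labelled trees ≤16 leaves; B = 100 bootstrap)
  were chosen as the smallest sizes at which the properties are
  informative.

# Known limitations

* The GPX tetrad reference and the PRX5 C_R context / a-b motif definitions
  are synthetic or provisional placeholders for curated data; the
  interfaces accept replacements.
* Manual curation steps of published surveys (structure-guided filtering of
  truncated catalases, alignment-informed GPX domain-structure filtering)
  are approximated by explicit, configurable rules (length floor; domain +
  tetrad checks) and will not reproduce hand-curated counts exactly.
* The internal tree builder is distance-based NJ with classical bootstrap;
  maximum-likelihood inference and model selection are intentionally
  external (import the newick).
* Localization is ingest-only: the package attaches an external predictor's
  compartments to calls and tallies them, it does not predict.
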