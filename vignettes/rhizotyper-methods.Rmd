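---
title: "Methods: typing, classifying and screening rhizobial collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typing, classifying and screening rhizobial collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotyper)
```

`rhizotyper` models the analysis arc of a trap-host rhizobium survey: many
nodule isolates are fingerprinted by IGS PCR-RFLP, representatives are
placed taxonomically by multilocus sequence analysis (MLSA) and symbiovar
typing, communities are related to soil and climate, and candidate strains
are scored for symbiotic performance and stress tolerance. This vignette
describes the models, their assumptions, the parameters that matter, and
the deliberate numerical choices.

## In-silico IGS PCR-RFLP

The 16S–23S rRNA intergenic spacer (IGS) is amplified (about 900 nt in
rhizobia) and digested separately with HaeIII (GG^CC), MspI (C^CGG) and
HhaI (GCG^C). `digest_amplicon()` treats the amplicon as a linear,
fully-digested molecule and scans a single strand only: all three
recognition sites are palindromic, so reverse-strand scanning would find
the same sites. Every site occurrence cuts (complete-digest chemistry,
including overlapping occurrences), and fragment lengths always sum to the
amplicon length. Ambiguity codes are rejected rather than expanded — the
typing convention assumes resolved Sanger consensus sequences.

A fingerprint is what a gel shows, not what the digest produces, so
`gel_model()` imposes two empirical parameters:

* `min_visible` (nt, default 100): fragments shorter than this run off the
  gel or stain too faintly to be called.
* `bin_tolerance` (fraction, default 0.05): two fragments co-migrate when
  their lengths differ by at most this fraction of the larger; co-migrating
  bands merge to their mean length (rounded to the nearest nt).

Neither value is standardised in the literature for 2.5 % agarose gels;
both are exposed in the configuration. Binning is agglomerative on sorted
lengths against the running bin mean and is iterated to a fixed point, so
re-binning a key reproduces it exactly — a property the type-grouping
relies on. IGS types are groups of isolates with *identical* keys across
all three enzymes, numbered by decreasing abundance (ties by first
appearance), so type 1 is always a most-abundant fingerprint. Cross-lane
tolerance matching (calling two *different* keys equal when every band is
within tolerance) is intentionally not performed: key equality stays exact
and transitive, and the generator guarantees identical digests within a
planted IGS class.

Representatives are drawn one per type from the type's most-populated site
(lexicographically smallest isolate id in that cell, for determinism), with
`extra_site_quota` further representatives from the next most-populated
sites when a survey samples types per site.

## MLSA species assignment

Species placement uses the concatenated recA–atpD–rpoB sequence (with the
standard amplicon trims, 289 + 297 + 599 = 1185 nt, concatenated in that
fixed order). Percent identity comes from a global Needleman–Wunsch
alignment with match +1, mismatch −1 and a linear gap penalty of −2 per
gapped column, with end gaps penalised; identity is matched columns over
the *full* alignment length, terminal gap columns included. That
denominator is one unambiguous convention among several in use; set
`include_terminal_gaps = FALSE` to exclude terminal gap runs instead.
Because co-optimal alignments can differ in match count, the aligner
canonicalises each pair (lexicographic order) before aligning, making
identity exactly symmetric. The kernel is compiled (Rcpp); the R oracle
used in the test suite is the Biostrings aligner under the same scoring.

Classification against a type-strain panel is nearest-neighbour with a
species boundary at 97.0 % identity on the concatenation. A strain exactly
at the boundary counts as *assigned* — the convention resolves in favour of
assignment, and the choice is logged in the assignment table by the exact
identity value. Identity is computed on the concatenation rather than
averaged per locus, matching how survey tables report a single MLSA
similarity per strain pair. Strains below threshold to every panel member
are *novel* and are clustered into genospecies by single linkage at the
same 97 % threshold, numbered by decreasing cluster size (then first
appearance) as Roman numerals. Single linkage is the natural choice here
because a genospecies is defined by a chain of above-threshold
relationships, not by a centroid.

16S rRNA grouping (`group_16s()`) is reported for context only: it builds a
neighbour-joining tree on 16S identity distances and groups leaves within a
configurable cophenetic depth (default 1 percentage point). It carries no
weight in species assignment — 16S is too conserved within *Rhizobium* to
separate close species, which is why MLSA is the decisive marker.

Symbiovars are orthogonal to core-genome taxonomy: `assign_symbiovar()`
gives each strain the symbiovar of its nearest nodC reference provided
identity reaches `min_identity` (default 90 %), else "unresolved". nifH is
typed with the same machinery and reported for concordance; discordant
nodC/nifH calls are flagged, never resolved automatically.

Trees are neighbour-joining on identity distances (`nj_tree()`), with
validation (symmetry, zero diagonal) and negative branch lengths clamped to
zero with a message. Maximum-likelihood inference, model selection and
bootstrap support are out of scope by design; NJ recovers the generating
topology for additive distances, which is the property the tests assert.

## Diversity and community–environment association

Alpha diversity is expressed as effective numbers of species (Hill
numbers): q0 = richness, q1 = exp of Shannon entropy in natural log units
(the natural log is required for exp(H) to be an effective number), q2 =
inverse Simpson. Raw counts are used — no rarefaction — because survey
tallies are reported as raw isolate counts; this means q0 is sensitive to
sampling depth, which is why the monotone profile q0 ≥ q1 ≥ q2 rather than
any single index is reported per site. Relative abundances are printed as
percentages rounded half-up to one decimal, matching the conventional
printed style (half-even rounding would print 28.75 % as 28.7 %).

Ordination is a centred PCA (unscaled singular value decomposition) of the
site-by-taxon composition, after either row-proportion or Hellinger
transformation. The proportion transform (default) matches the biplot
semantics of relating *composition* to environment; Hellinger is offered
because it makes PCA respect ecological distances better when abundant and
rare taxa are mixed. Soil and climate variables never enter the
decomposition: they are standardised and correlated with the site scores
afterwards (supplementary-variable arrows), so the ordination reflects
community structure alone. Axis signs are fixed by making the first
nonzero taxon loading of each axis positive. Bray–Curtis dissimilarity is
provided for distance-based views of the same table; constrained
ordination (RDA/CCA) and axis permutation tests are out of scope.

## Symbiotic performance score

For each bean variety, each treatment's mean nodule count, mean SPAD
reading and mean total dry biomass (shoot + root per plant) are divided by
the best treatment mean of that trait in the experiment, giving indices in
[0, 1] with 1 for the best performer. The composite score is

score = 100 × (0.25 · nodulation + 0.25 · chlorophyll + 0.5 · biomass)

Biomass is weighted double because dry-matter gain is the agronomic
endpoint; nodulation and greenness are mechanistic proxies. The
uninoculated control (CK) takes part in the best-mean scan like any other
treatment — it cannot win nodulation (zero nodules by definition of a clean
control) and rarely biomass, and treating it uniformly keeps the scoring
code path single; the behaviour is configurable in principle by filtering
the input table. The score is scale-invariant: rescaling every replicate of
every treatment by a positive constant leaves all indices unchanged.

Significance letters come from one-way ANOVA and pairwise Fisher LSD tests
on the pooled mean-square error at α = 0.001 (deliberately conservative for
many pairwise contrasts without multiplicity correction), displayed as a
compact letter display: treatments sorted by descending mean, letters
assigned by the insert-and-absorb construction so that two treatments share
a letter exactly when the LSD test cannot separate them. For the letter
display the ANOVA runs on replicate-level scores (each plant standardised
against the best treatment means), whose treatment means equal the
composite scores. When every group has zero within-group variance the
F test is undefined; the display falls back to exact mean equality with a
message rather than failing.

## Stress screens

The five condition families replicate standard plate/broth screens: pH 5,
6, 7, 8, 9, 10, 11 (control 7); NaCl 0.01, 1, 2, 3, 4 % w/v (control
0.01); temperature 4, 10, 28, 37, 45 °C (control 28); PEG 6000 0, 3, 5, 7,
10, 15 % w/v (control 0); glyphosate 0, 0.6, 1.2, 1.8 mL/L of a 41 %
commercial solution (control 0). Growth is called per strain against that
strain's own control mean: `normal` at ≥ 80 %, `none` at ≤ 20 %, `weak`
between. The 0.8/0.2 thresholds are package defaults for quantitative
inputs — plate screens are recorded qualitatively and no standard numeric
cut exists — and raising `normal_frac` can only shrink the normal set, a
monotonicity the tests assert. Strains whose control fails are excluded
with a warning, not silently scored.

Ranking is by tolerance breadth (non-control levels passed), ties broken by
the number of *extreme* levels passed (pH 11, 45 °C, 2 % NaCl, 10 % PEG,
1.8 mL/L glyphosate — the harshest informative level of each family), then
by strain id. Elite strains are the intersection of three top-k sets:
composite score on variety 1, composite score on variety 2, and tolerance
rank. The intersection may legitimately be empty.

## The synthetic community generator

`gen_community()` is first-class, tested code, not a fixture: it emulates a
multi-site trap-host collection with known truth so every downstream stage
has a planted answer.

*Sequence model.* All species descend from one random ancestor per locus.
Each species consensus mutates the ancestor on its own disjoint block of
positions (half the between-species divergence each), so any two species
differ by at least `between_species_divergence` — exactly, up to the rare
back-mutation from strain-level noise. Strains mutate their consensus at
half the within-species divergence, bounding within-species pairs by
`within_species_divergence`. Substitutions are uniform over the three
alternative bases; there are no indels at MLSA loci by default, no rate
heterogeneity and no recombination — identity and alignment behaviour stay
well-posed, which is the point of the generator, and is also its main
departure from real molecular evolution. The defaults (1 % within, 6 %
between and novel) put named strains at ≈ 99.5 % to their own type strain
and ≈ 94 % to everything else, and novel clusters below 97 % to every
panel member, i.e. comfortably on the correct side of the species boundary
with realistic margins.

*IGS classes.* Each species carries its own IGS layout: one HaeIII site at
a class-specific offset (150 + 40·(class − 1); 40 nt spacing exceeds the
5 % gel tolerance at these fragment sizes, so classes never co-bin) plus
fixed MspI and HhaI sites. Backbones are scrubbed of accidental
recognition sites, and strain-level IGS mutations avoid the planted site
windows and are rejected if they would create a new site — members of a
class therefore share one fingerprint at any noise level, which is what
makes IGS type a faithful proxy for species in the synthetic world (real
surveys see several IGS types per species; the pipeline handles that, the
generator simply does not plant it).

*Community.* Defaults are a 46-isolate, 15-site collection (4 isolates at
the first site, 3 elsewhere) over 16 species: 11 named panel species and 5
novel clusters. The allocation keeps species 1 strictly most abundant (so
"type 1 is the most abundant" has a planted answer), gives the designated
sv. viciae species exactly 2 strains (a 44/2 symbiovar split at the
46-strain scale), and spreads the remainder decreasingly. Equal-ish
isolates per site is a choice, not an observed fact — surveys report only
totals. When a soil table is supplied, the first species' strains are
allocated to sites with probability proportional to exp(β·z(pH)) (β = 1.5
by default), planting the pH gradient the ordination tests look for.

*Phenotypes and stress.* Phenotypes are multiplicative:
baseline × effect × (1 + N(0, noise)), truncated at zero, with baselines
of 55 nodules, SPAD 30, 1.5 g shoot and 0.5 g root dry weight — typical
inoculated-bean magnitudes. Planted "efficient" strains get ×2.8 biomass
and ×1.3 nodulation/chlorophyll; CK is an ordinary treatment class with
zero nodules, so scoring code paths are uniform. Stress envelopes are
planted at the per-level pass fractions of a 46-strain screen (all at the
controls; none at pH 5 or 4–10 °C; 21/46 at pH 6 down to 9/46 at pH 11;
17/46 at 1 % NaCl; 12/46 at 37 °C and 3/46 at 45 °C; 31/46 and 11/46 at
7 % and 10 % PEG; 38/46 and 27/46 at 1.2 and 1.8 mL/L glyphosate), nested
within each family via a single random strain order, so a strain passing a
harsh level passes the milder ones. Passing cells draw growth around 1.0,
failing cells around 0.05 — far from the 0.8/0.2 call thresholds, so calls
are exact at zero noise and robust at the default 2 % noise.

All randomness in a generator call flows from the single seed in its
configuration; identical configurations are byte-identical in output.

*What passing tests do and do not show.* Recovery of planted labels under
this generator demonstrates that the pipeline machinery is correct and
deterministic, with margins (2.5 percentage points to the species
boundary) that tolerate the planted noise. It does not demonstrate
performance on real data, where divergences are not block-disjoint,
IGS types cut across species, indels and chimeras occur, and phenotype
noise is not i.i.d. multiplicative.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full pipeline on the
default 46-isolate community over 5 seeds, the digest-versus-scanner
comparison on 1000 random sequences up to 2000 nt, Hill-number
monotonicity on 1000 random count vectors, and identity symmetry on 200
random pairs — sizes chosen so the complete suite runs in about a minute
while still exercising every code path at survey-like scale.

Other numerical choices: half-up rounding for printed percentages; bin
means rounded half-up to integers; Bray–Curtis is an error only when two
all-empty sites make the pair undefined (a single empty site is distance 1
to everything); constant environmental variables get zero-length arrows
with a warning instead of NA; PCA of a constant matrix reports zero
variance on every axis rather than NaN; an asymmetric distance matrix is
an error, but negative NJ branch lengths (a known NJ artefact) are clamped
to zero with a message.

## Known limitations

* Exact-equality fingerprint keys: band patterns from *different* digests
  are never matched with tolerance across isolates; real gel-lane matching
  would need a band-registration step.
* The species boundary is a single global identity threshold; no
  per-species thresholds, no codon-aware alignment, no recombination
  screening.
* NJ trees only; no ML inference or bootstrap support.
* Ordination is unconstrained PCA/PCoA; environmental variables are
  passive.
* The LSD letter display deliberately applies no multiplicity correction
  beyond its conservative α.
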