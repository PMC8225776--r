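---
title: "Methods: screening Red List narratives for threats from an invasive species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening Red List narratives for threats from an invasive species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatminer)
```

## The problem

Comprehensive extinction-risk databases carry, for each assessed taxon, a
free-text narrative describing its major threats. Screening those
narratives is the standard way to quantify how many taxa a widespread
invasive species — here, by default, the wild pig *Sus scrofa* — is
documented to threaten, which taxonomic groups and regions bear the
brunt, and through which mechanisms. threatminer implements that
workflow end to end: keyword screen, curated review, rule-based
severity and mechanism classification, geographic stratification, and
descriptive summaries.

The package never touches a live database. Its inputs are four plain
tables — a taxon corpus, a focal-species range map, a region table and
a curation file — and it ships a seeded generator that produces
corpora of the same shape with known ground truth, so every stage is
testable without redistributing copyrighted assessments.

## Keyword screen

The screen runs over `threats_text` only (the major-threats narrative),
not over range descriptions. Text is tokenized into maximal runs of
letters; digits, hyphens and punctuation separate tokens, and matching
is case-insensitive. The default pattern set holds ten literals (pig,
pigs, domesticus, sus, scrofa, boar, boars, hog, hogs, swine) and
three wildcards (`pig*`, `boar*`, `hog*`). A wildcard matches any —
possibly empty — letter suffix, so `pig*` covers pig, pigs, piglet and
also pigeon and pigment. That over-matching is deliberate: the
workflow is flag-then-review, and nothing is auto-excluded at screen
time. Each flagged record carries its matched tokens, offsets and
patterns, plus a `prefix_only` flag marking records whose every hit
came through a wildcard with no literal — the classic false-positive
signature that reviewers triage first. The tokenizer and case rules
are package conventions, declared here; `swine` carries no wildcard
because the pattern list gives it none.

## Review and classification

The curation file is a structured stand-in for two-reviewer manual
reading. Verdicts remove false positives; confirmed records carry
evidence cues and, optionally, a stated severity grade. Two cue types
take a record out of the analysis entirely even when confirmed as
genuine pig mentions: hunting pressure catalyzed by the presence of
pigs, and domestic pigs not described as free-ranging. We generalize
"only" slightly: a record is excluded when its cue set is non-empty
and contains nothing but these out-of-scope cues.

Severity is graded major / minor / potential by an ordered rule table:

1. a stated grade always wins — sufficient narrative detail overrides
   any default;
2. evidence consisting solely of range overlap grades *potential*
   (the threat was inferred from co-occurrence, not documented);
3. EX, EW and CR taxa grade *major* — any threat mention to a taxon at
   or past the brink counts as major;
4. LC taxa grade *minor* by default, as do
5. NT taxa (secondary-threat status is not separately encoded, so the
   NT default collapses to minor unless a grade is stated);
6. EN, VU and DD taxa grade *major* when any direct-impact cue is
   present, otherwise *potential*.

Rule 6 is a declared package convention: the source rules state
defaults only for EX/EW/CR, LC and NT, and we resolve the gap by
mirroring the CR treatment (at-risk status plus direct evidence)
while keeping undocumented impacts potential. Placing rule 2 before
rule 3 means bare overlap-only evidence yields *potential* even for a
CR taxon; we read an overlap-only judgement by the curator as exactly
the "sufficient detail to categorize otherwise" that the rules allow.

Mechanisms map from cues mostly one-to-one (predation, disturbance,
disease risk, competition, hybridization), with two compound rules:
consumption of a plant counts as both predation and disturbance (the
individual is eaten and the vegetation structure altered), and nest
digging for reptiles, amphibians and ground-nesting birds counts as
both predation and disturbance (direct mortality plus destruction of
the nest site). Two further conventions cover cases the rules leave
open: consumption of a non-plant maps to predation only, and nest
digging for other classes maps to disturbance only. Overlap-only
evidence defaults to disturbance. Every confirmed record must end up
with at least one mechanism; an empty set is an error, not a silent
drop.

## Geography

Admin-unit codes are opaque strings matched exactly; sub-country units
are just more codes, with no modelled hierarchy — the range and region
tables must use the same code set as the corpus. Each record's region
set is the image of its units under the region table (17 regions in
the default configuration, 8 island and 9 continental). Because
country-level range data cross-list island endemics under the
continental country that governs the island, a structured
`endemic_to` field collapses the region set to the single home region;
an `endemic_to` naming a region the taxon is not even assigned to is an
inconsistent record and errors. Endemism is a structured field rather
than parsed from the range narrative because that resolution was a
manual judgement in the original workflow; no heuristic parser is
authoritative.

Range overlap is computed per unit: a taxon is in the native
(non-native) range when any of its units carries that status; taxa
overlapping both are tallied in both. Taxa whose units are exclusively
outside all range classes are excluded. Taxa retained only through
units where the focal species *potentially* occurs are kept only if at
least one such unit hosts a confirmed threatened taxon; one pass
suffices because removals can never create new threatened taxa.

For the island/continental comparison, a taxon with any continental
region is continental; an island endemic whose regions are all islands
forms the island stratum. A non-endemic taxon occurring only on
islands belongs to neither stratum — the island comparison is
endemics-only by design — though it still counts in corpus-level
tallies.

## Summaries

Corpus-level tallies count each threatened taxon once per category,
reporting group (reptiles and amphibians pooled as herpetofauna) and
severity, and once per mechanism (so mechanism totals can exceed the
taxon count). Per-region proportions are threatened / assessed within
each (region, group) cell; cells with no assessed taxa are omitted.
The quotient is deliberately threatened over total — the direction
every reported percentage implies — with denominators drawn from the
retained corpus (after range exclusion), island regions restricted to
their endemics. Island and continental summaries report the mean and
the *sample* standard deviation (n − 1 divisor, `stats::sd`) of
per-region proportions, per group and pooled; with a single
contributing region the SD is undefined and reported as 0 with an
explicit `sd_defined = FALSE` flag. Percentages in human-readable
output are rounded half away from zero to whole percent; raw
proportions are retained in machine output.

Two comparator profiles reproduce the inclusion criteria of earlier
invasive-predator syntheses so totals are directly comparable: one
keeps reptiles, birds and mammals above NT status; the island variant
additionally keeps only island endemics.

Every assembled report is validated against its arithmetic
invariants — group and severity counts sum to the threatened total,
severity percentages sum to 100, proportions lie in [0, 1], and the
native + non-native − both identity holds — on every build, not just
in tests.

## The synthetic generator

`generate_corpus()` draws a seeded corpus over the shipped 17-region
configuration. Defaults were chosen once as the study conditions: a
plant-heavy group mix (35% plants, 20% herpetofauna, 15% birds, 18%
invertebrates, 12% mammals), a Red-List-like category marginal
dominated by LC and DD, per-group threat rates of 8–20% so a clear
minority of narratives mention the focal species, a 59/21/20
major/minor/potential severity split, cue profiles dominated by
disturbance and predation, a 5% distractor rate (pigeon, pigment,
pigtail, hogweed — tokens that trip a wildcard without a literal), 50%
continental cross-listing of island endemics, a 35% island-endemic
fraction, and small rates of out-of-scope mentions (2%), out-of-range
taxa (4%) and potential-only taxa (3%). One pseudo-random stream,
seeded from the configuration, is consumed in a fixed per-taxon order
— class, family, category, placement and units, threat flag,
out-of-scope flag, cues and severity, narrative — so identical
configurations yield byte-identical corpora. The category marginal is
a single distribution because the draw order fixes category before the
threat flag; the category-dependence of *severity* still emerges
through the grading rules. Narratives are plain template sentences,
not database text, to avoid redistributing copyrighted assessments.

Ground-truth severities and mechanisms are generated to be consistent
with the package's own rule tables (a drawn target severity is
realised through a stated grade whenever the category default would
differ). The closure property — the end-to-end pipeline on the emitted
CSV files, with the oracle curation, reproduces the ground-truth
summary exactly, including island/continental means and SDs — is the
principal end-to-end check, and it verifies the plumbing: screening,
review, classification, geographic resolution, range exclusion and
file round-trips. The rule tables themselves are verified separately
against independent oracles (a brute-force per-pattern regex scan for
the matcher; transliterated rule tables for severity and mechanisms).

What the generator does *not* emulate: real narrative prose (templates
are single sentences, so the screen's precision on real text will be
lower and the review queue relatively larger), correlated taxonomy and
geography (families are drawn independently of region), assessment
gaps and data-deficiency biases, or the marginal distributions of any
particular database snapshot. Passing tests therefore demonstrate the
pipeline's correctness on structurally faithful inputs, not the
reproduction of any published corpus-dependent count.

## Problem sizes and numerical choices

The test suite exercises corpora of 60–5,000 taxa; the closure
property is asserted at n = 500 through the on-disk CSV dialects and
at n = 5,000 in memory, sizes at which every stratum and rule branch
is populated many times over. Comparisons of derived doubles use a
1e-12 tolerance; all counts are compared exactly. Ties never arise in
the rule engine (rules are ordered, not weighted), and the only
degenerate numerical case — a stratum with one contributing region —
is handled by flagging the SD as undefined rather than emitting `NA`
into downstream arithmetic.
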