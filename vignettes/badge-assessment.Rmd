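---
title: "Assessing sequence-data and metadata availability with tiered badges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing sequence-data and metadata availability with tiered badges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbadge)
```

## The assessment model

`seqbadge` evaluates open-data compliance of publications that report
amplicon (marker-gene) or metagenome sequence data. The unit of assessment
is one publication; the output is an ordinal badge — None, Bronze, Silver,
Gold, or *cannot be determined* — plus a per-criterion ledger that makes the
assignment auditable.

The model separates three concerns:

1. **Evidence extraction** turns article text into discrete observations:
   accession tokens with their registry, primer sequences, a
   sequencing-method class, code links, and a data-availability-statement
   (DAS) class.
2. **Repository resolution** turns accession tokens into facts about the
   deposited data: public or not, run counts, raw file formats. Prose claims
   of deposition are deliberately never trusted for these facts — only
   resolved repository records (or, offline, a fixture manifest) decide
   downloadability and raw-format status.
3. **The badge rules** map the assembled boolean evidence to the badge.

A key normative choice: the requirement table is cumulative and
downloadability is required at *every* tier. A looser reading would allow
Silver for well-described but access-restricted data; we instead represent
restricted-but-documented access only through the Gold-tier "access
requirements clarified" alternative, because a machine-checkable standard
needs the table, not the narrative, to be authoritative. A consequence worth
knowing: once Bronze holds, the Gold clause "public **or** access
clarified" is automatically satisfied, so in practice Gold hinges on
repository openness and code availability.

## Evidence extraction: parameters and guards

All catalogues ship as editable YAML under
`system.file("extdata", "config", package = "seqbadge")`.

* **Accessions.** Word-boundary-anchored patterns for INSDC BioProjects
  (`PRJNA`/`PRJEB`/`PRJDB`), studies, samples, experiments and runs, plus
  CNCB-NGDC (`PRJCA`, `CRA`), MG-RAST (`mgm...x.y`), EGA (`EGAS`/`EGAD`,
  11 digits) and CNGB (`CNP`). Minimum digit counts (5 for runs, 4
  elsewhere) block gene-symbol collisions such as `SRP54`; hits are
  deduplicated on token and reported with 0-based half-open spans.
  Dash-joined token pairs are flagged as range endpoints and never
  expanded — expansion would require a registry lookup. Which record types
  count as "accession provided" is unspecified in checklist practice; we
  accept any catalogued type and record the type, so callers can be
  stricter.
* **Primers.** Candidates are IUPAC-nucleotide runs (15-letter alphabet,
  any case) of length ≥ 12. Real primers are usually ≥ 15 nt; 12 buys
  recall because the precision work is done by a context guard: a primer
  keyword (primer/forward/reverse, 16S/18S/ITS, V1–V9, a `515F`-style
  label) within 200 characters. `16S`, `18S`, `ITS` and `WGS` are matched
  case-sensitively throughout the lexicons — otherwise every English "its"
  would read as a marker gene. Primer *sequences* themselves are matched
  case-insensitively, which is a contract the noise machinery relies on.
* **Sequencing method.** Two keyword lexicons mirror the marker-gene vs
  metagenomics dichotomy; matches in both yield `both`, in neither
  `unknown`. Method statements recovered from repository metadata are also
  acceptable evidence; both sources feed the same boolean.
* **Code links.** URLs on catalogued code hosts always count; other URLs
  only with a code keyword within 200 characters, which keeps
  institutional-homepage links out.
* **DAS class.** Trigger phrases per class, scanned in fixed precedence
  `public_deposit` > `restricted_with_procedure` > `upon_request` >
  `in_paper_only`. Precedence rather than first-occurrence makes mixed
  statements ("deposited in the SRA; other materials upon request")
  resolve to the strongest claim. When no dedicated DAS section exists the
  full text is scanned instead.

## The badge rules and their invariants

`assign_sequence_badge()` is a total function over valid evidence bundles
(the only validity constraint: public downloadability implies an
accession). Two exhaustively tested invariants document its shape:

* **Tier subsumption** — a Gold report satisfies every Silver and Bronze
  requirement.
* **Monotonicity** — upgrading any piece of *evidence* from absent to
  present never lowers the badge. `is_amplicon` is excluded from this
  property by design: it is a study descriptor, not openness evidence, and
  discovering that a study is amplicon-based legitimately *adds* the primer
  requirement. `cannot_be_determined` is ranked below None for this check,
  since learning the full text exists can only improve matters.

The primer criterion is marked `not_applicable` (not `satisfied`) for pure
metagenome studies, and similarly the Gold access-clarity criterion when
data are already public; `not_applicable` never blocks a tier but is
visible in the report.

## Metadata tiers and analytics

The packaged checklist is the human-gut flavoured prototype: 9 Bronze
fields (sample name, project name, taxonomy ID, collection date,
latitude/longitude, country/region, broad- and local-scale environmental
context, environmental medium), 8 more for Silver (sequencing method
through host sex) and 5 more for Gold. Canonical attribute names are MIxS
v6.0 short terms (`seq_meth`, `env_broad_scale`, ...); other environment
packages are drop-in YAML files.

Decisions a user should know:

* **Harmonization** matches case- and separator-insensitively; only the
  `"Sample Name"`/`"User_sample_ID"` pair among the defaults is documented
  in survey literature, the rest are implementation-supplied and marked as
  such in the config. When two raw names collapse within a sample, the
  first non-missing value wins and the collision is counted.
* **Completeness threshold** for a field to count: 100% of samples
  non-missing. The standard itself names no threshold; strict-but-
  configurable (`threshold` argument) is the transparent default.
* **Missing-value vocabulary**: `""`, `na`, `n/a`, `nan`, `missing`,
  `not applicable`, `not collected`, `not provided`, `unknown`, `-` —
  the INSDC reporting vocabulary.
* The metadata badge is assessed **per study** (the per-sample alternative
  is undefined for study-level fields); value-format validation (ISO dates,
  decimal degrees) is out of scope for the tier and would be reported as
  warnings only.
* The article-assessment pipeline does **not** fold metadata badges into
  its default output; metadata assessment is a separate command and
  library surface, reflecting how heterogeneous real submissions are.

Cross-study analytics: `population_matrix()` marks an attribute populated
for a study when ≥ 1 sample is non-missing, `sparsity_histogram()` bins the
per-attribute proportions (left-open/right-closed, first bin includes 0),
and `median_population()` reports the median proportion.

## Evaluation conventions

`evaluate()` computes accuracy, per-class precision/recall/F1 with support,
macro-average F1 and weighted F1. Conventions, chosen once and used
everywhere: F1 is 0 when precision + recall is 0; macro averaging runs over
the classes present in the truth labels unless a class list is supplied;
weighted F1 weights by truth support (the standard convention);
`cannot_be_determined` items are excluded from accuracy by default, with
explicit flags to include them (as their own class four-way, as
`not_badged` in the binary view). The binary collapse can only preserve or
create agreement, so binary accuracy always dominates four-category
accuracy — a property the test suite checks on random label sets.

## What the synthetic corpus does and does not show

`generate_corpus()` writes seeded JATS articles whose text embeds exactly
the evidence implied by a target badge, plus the offline manifest that
makes resolution consistent with it. Defaults are fixed study conditions,
not tuning knobs: the badge mix (45% None, 15% Bronze, 27% Silver, 8%
Gold, 5% not determinable) and the registry weights (SRA-dominated, then
ENA) follow the proportions reported by field surveys of microbiome
publications; 70% of articles are amplicon studies; None articles rotate
through their three causes (no accession / private / non-raw formats), and
not-determinable articles through missing, truncated, and bodyless full
text.

Noise options are restricted to transformations the extractors are
*contracted* to tolerate — primer case jitter, punctuation spacing, section
reordering — so round-trip accuracy on noisy corpora must stay at 100%.
Adversarial noise (accessions split across line breaks, OCR artefacts,
free-prose DAS phrasing outside the phrase table) is deliberately absent.
Passing the round-trip therefore shows the pipeline is internally
consistent and lossless on clean, templated evidence; it does **not**
estimate accuracy on real literature, where phrasing varies freely and
errors concentrate in adjacent-tier confusions rather than in the binary
None-versus-Badged split.

The metadata generator plants a sparsity profile emulating cross-study
surveys: 16 consistently filled attributes, a long tail (167 of 220)
populated by a single study each, and a middle band. Realized population
counts are recorded exactly, so recovery tests are exact (`identical`), not
approximate. Generated values are plausible strings, not ontology-resolved
terms.

## Numerical and degenerate-input choices

Empty text yields empty hit tables, never errors. Extraction on a document
without full text signals a typed condition
(`seqbadge_not_determinable`); empty studies and empty study lists signal
`seqbadge_unevaluable`; batch assessment converts per-item failures to
data rows and never aborts. Histogram bin edges must strictly increase and
span [0, 1]. Offsets are 0-based half-open so span tests are unambiguous.
Per-article generator seeds are drawn below 2^31 from the corpus seed;
identical seeds give byte-identical fixtures.

Problem sizes used by the test and acceptance suites — chosen to exercise
every path at comfortable margins: exhaustive enumeration of all 768 valid
evidence bundles; 200-article corpora per noise option; metric-oracle
agreement over all label multisets up to n = 6 (74,612 cases — exhaustive
up to permutation, with permutation invariance tested separately); 1000
random label sets for collapse dominance; and the full 42 × 220 metadata
survey.

## Known limitations

* The extractors are pattern-based; paraphrased availability statements
  outside the phrase table fall back to `absent`, and accession ranges are
  reported as endpoints only.
* GenBank/GEO-style tokens are excluded from the default catalogue (they
  are not raw-read registries); projects that deposit only assemblies will
  read as lacking accessions unless the catalogue is extended.
* The live clients cover PMC full text and ENA-style resolution behind a
  narrow contract; they are polite (rate-limited, contact header) but
  minimal, and the offline fixture mode is the tested contract.
* The metadata checklist is a human-gut prototype; other environments need
  their own checklist file, and ontology-term resolution (ENVO/UBERON) is
  out of scope.
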