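---
title: "Trait-rule categorization of denitrification potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-rule categorization of denitrification potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitrait)
library(dplyr)
```

## The model

Denitrification is a strain-level ecological trait: the four reduction
steps (nitrate → nitrite → nitric oxide → nitrous oxide → dinitrogen) are
each catalyzed by dedicated reductases, and a genome's *potential* to run
a step can be read off the presence or absence of the genes encoding
those reductases. `denitrait` operationalizes this as a two-stage binary
coding:

1. **Enzyme pattern.** Twelve genes in a fixed catalog order — narG,
   narH, narI, napA, napB, nirK, nirS, norB, norC, norV, norW, nosZ —
   give a 12-digit presence/absence string, one of 4096 possibilities.
2. **Step pattern.** A trait rule set reduces the enzyme pattern to four
   digits, one per reduction step. A step digit is 1 iff at least one of
   the step's *enzyme complexes* is completely present:
   narGHI or napAB (nitrate), nirK or nirS (nitrite), norBC or norVW
   (nitric oxide), nosZ (nitrous oxide).

The complex requirement is a hard rule, not a heuristic. A genome with
norB but not norC cannot assemble the cytochrome-c nitric oxide
reductase, so its step-3 digit stays 0 — e.g. the Haloferax volcanii DS2
pattern:

```{r}
apply_trait_rules("110001010000")
```

Similarly napB without napA does not satisfy the nitrate step:

```{r}
apply_trait_rules("000010111000")  # napB orphan; nirS + norBC present
```

The 16 step patterns map to named traits. Names are generated
compositionally — the satisfied step names joined with commas and a final
"and", suffixed "Reduction Only" — with two fixed endpoints, "Incomplete
Enzymes for Denitrification Steps" (0000) and "Complete Denitrification"
(1111). We chose the no-Oxford-comma form as canonical and compare names
case-insensitively (`trait_code()`), since equivalent phrasings circulate
with and without the serial comma.

```{r}
trait_name(c("0001", "0101", "1011", "1111"))
```

### Structure of the rule space

The rule map is total: all 4096 enzyme patterns are classified, including
the all-zero pattern (mapped to 0000) even though the dataset builder
excludes gene-free genomes — keeping the engine total makes it usable on
arbitrary inputs and trivially testable. Each step is independently
satisfiable, so all 16 codes are reachable. Preimage sizes follow from
per-step counting: 11 of the 32 assignments over the five nitrate-step
genes satisfy narGHI ∨ napAB, 3/4 satisfy the nitrite step, 7/16 the
nitric-oxide step and 1/2 the nitrous-oxide step, so e.g. the complete
trait has 11 × 3 × 7 × 1 = 231 preimages:

```{r}
map <- enumerate_rule_map()
preimage_counts(map)
```

Rule sets are data, not code: `trait_ruleset()` accepts any catalog and
any step/complex structure, serializes to YAML (`write_ruleset()` /
`read_ruleset()`), and the same engine evaluates the included
nitrogen-fixation rule set (structural NifHDK, biosynthetic NifENB):

```{r}
tidy(nif_ruleset())
```

## From portal exports to the annotated dataset

The ingest layer reads per-KO genome lists in the IMG/M export dialect
(columns Domain, Status, Genome ID, Genome Name; tab- or comma-
separated) labelled `01_narG` … `12_nosZ`, merges them into a genome ×
enzyme presence matrix, and joins a metadata table carrying GTDB-Tk
lineage and the GOLD 5-level ecosystem classification. Design choices
where the upstream conventions are loose:

* **Genome identity is the Genome ID**, never the name. When lists
  disagree on a genome's name the first-seen value wins and the conflict
  is reported as a warning.
* **Presence is boolean.** Duplicate rows within one KO list collapse to
  a single membership with a warning.
* **Whitespace is normalized** (trimmed, internal runs collapsed) before
  genus derivation and replicate detection, since export dialects vary.
* **Genus is the text before the first space** of the genome name. This
  literal rule mis-assigns "Candidatus ..." names (genus "Candidatus");
  we keep it literal because it is the documented derivation and is
  transparent to downstream users.
* **Missing annotation stays `NA`** in the dataset and is rendered as
  the explicit label `"Null"` in grouped summaries.

`build_dataset()` enforces the inclusion criterion — at least one of the
twelve genes present — excluding all-zero genomes with a reported count,
and guarantees the self-consistency invariants: the stored 12-digit
pattern equals the concatenated enzyme digits, the stored 4-digit code
equals the rules applied to it, and the stored trait name equals
`trait_name()` of the code. Replicate strains (one normalized name,
several Genome IDs) are tabulated by `detect_replicate_strains()`.
Exports are CSV/TSV with display headers; pattern columns are typed as
text on re-import so leading zeros ("0100") survive the round trip. A
spreadsheet writer is deliberately not offered: delimited text is the
lossless interchange format here, and spreadsheet numeric coercion is
exactly what corrupts pattern strings.

## The synthetic cohort generator

`generate_cohort()` emulates the input side of the pipeline: it plants a
known trait distribution and emits the same files a portal export would
give — twelve labelled KO lists, a metadata table — plus the truth table.
What it emulates, and what it does not:

* **Trait distribution**: genomes are assigned 4-digit codes by the
  spec's `trait_weights`. The default is the published archaeal
  distribution (866 genomes over 9 of the 16 codes, dominated by
  nitrite-only and incomplete categories); any weighting over the 16
  codes can be planted.
* **Within-trait patterns are uniform over the code's preimage** (minus
  the all-zero pattern, so every emitted genome meets the inclusion
  criterion). Real genome collections concentrate on a small fraction of
  the 4096 patterns, so uniformity is unrealistic, but it maximizes
  coverage of rule-engine edge cases, which is the generator's job.
* **Replicates**: with probability `replicate_rate` (default 0.03) a
  genome re-sequences an earlier strain — same name, taxonomy, ecosystem
  and enzyme pattern, new Genome ID — mirroring how culture collections
  deposit multiple sequences per strain.
* **Ecosystem annotation is missing at rate 0.4** by default, matching
  the roughly 40% unannotated fraction typical of large genome
  collections; taxonomy comes from a small fixed pool of realistic
  bacterial and archaeal lineages.
* **Not emulated**: real taxonomic abundances, correlations between
  taxonomy and trait, genome-quality artifacts (fragmented assemblies
  losing genes), or annotation error. Passing end-to-end recovery
  therefore demonstrates pipeline correctness — ingest, merge, join and
  build reproduce planted attributes exactly — not robustness to noisy
  annotation.

Generation is fully seeded; one spec yields byte-identical files.

```{r}
spec <- cohort_spec(seed = 1, n_genomes = 200)
truth <- generate_cohort(spec)$truth
count(truth, code, trait, sort = TRUE)
```

## Numerical and testing choices

Test problem sizes are kept small because the quantities of interest are
exact: the rule engine is verified by brute force on all 4096 patterns
against an independently coded oracle, the curated archaeal records (9
trait exemplars, 21 nirK+nirS genomes) are fixed inputs, and end-to-end
recovery uses cohorts of 400–1000 genomes, which already exercise
replicates, missing annotation and all planted codes. The convergence
check of empirical trait frequencies to planted weights uses a chi-square
goodness-of-fit at n = 10,000 with a loose p > 0.001 bound — it is a
sanity check on the sampler, not an estimate.

Degenerate inputs are defined rather than rejected where a definition is
natural: the all-zero pattern classifies to 0000; an empty KO list is a
valid (warned) input meaning no genome carries that gene; an empty genome
name yields an empty genus with a warning. Errors are reserved for
contract violations: unknown gene symbols, malformed patterns (with the
position of the first offending character), duplicate metadata IDs,
mislabelled dataset files.

## Limitations

Presence/absence of annotated KO terms is the sole evidence: the package
does not infer gene presence from sequence, and genomic potential is not
functional performance — regulation, environmental conditions and enzyme
kinetics decide whether a "1111" genome actually denitrifies. Draft
genomes may lack genes through assembly gaps rather than true absence;
the sequencing-status column is carried so users can filter on it.
Trait rules capture the canonical twelve genes only; alternative subunits
or lineage-specific reductase variants are not modelled.
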