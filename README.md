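# denitrait

Digital categorization of microbial genomes by denitrification potential.

Complete denitrification is the four-step microbial reduction of nitrate to
dinitrogen gas (NO3- → NO2- → NO → N2O → N2). Whether a genome can catalyze
each step is inferable from the presence or absence of twelve enzyme genes:
the nitrate reductases (*narG*, *narH*, *narI*, *napA*, *napB*), the nitrite
reductases (*nirK*, *nirS*), the nitric oxide reductases (*norB*, *norC*,
*norV*, *norW*) and the nitrous-oxide reductase (*nosZ*). `denitrait`
encodes a genome's gene complement as a 12-digit binary **Denitrifying
Enzymes Pattern** in that fixed order, reduces it to a 4-digit
**Denitrification Pattern** — step *k* is '1' iff at least one complete
enzyme complex for that step is present:

```
step 1 (nitrate):       narG ∧ narH ∧ narI   ∨   napA ∧ napB
step 2 (nitrite):       nirK                 ∨   nirS
step 3 (nitric oxide):  norB ∧ norC          ∨   norV ∧ norW
step 4 (nitrous oxide): nosZ
```

— and names one of the 16 resulting denitrification traits, from
"Incomplete Enzymes for Denitrification Steps" (0000) through "Complete
Denitrification" (1111). Partial complexes count for nothing: *napB*
without *napA*, or *norB* without *norC*, leaves the step digit at 0.

The package is aimed at microbial ecologists assembling trait-annotated
genome collections (for example, screening candidate strains for synthetic
denitrifying communities, or interpreting nitrogen cycling potential in
host-associated microbiomes). It provides:

* the **rule engine**: pattern encoding/parsing, trait rules as data
  (generic over gene catalogs — a nitrogen-fixation rule set over
  *nifHDK*/*nifENB* is included), trait naming, and brute-force
  enumeration of the full 4096-pattern space with preimage counts;
* **ingest** for IMG/M-style per-KO genome list exports and genome
  metadata tables (GTDB-Tk lineage, GOLD 5-level ecosystem), merged into
  a genome × enzyme presence matrix;
* **dataset assembly**: the 36-column annotated dataset, replicate-strain
  detection, grouped summaries, filtering, auxiliary-KO annotation
  (e.g. *glnA*, *nifH*) and lossless CSV/TSV export;
* a **synthetic cohort generator** that emits IMG/M-dialect inputs with a
  planted trait distribution, taxonomy, ecosystems, replicate strains and
  auxiliary-KO carriers, plus the truth table for end-to-end validation;
* **link builders** for Google Scholar gene-symbol searches (including
  negation queries such as `("absence of nosZ" denitrification)`) and
  IMG/M per-KO portal URLs.

## A worked example

The oyster-gut isolate *Arcobacter* sp. LA11 carries *napA*, *napB*,
*nirS*, *norB*, *norC* and *nosZ*:

```r
library(denitrait)

pat <- encode_pattern(c("napA", "napB", "nirS", "norB", "norC", "nosZ"))
pat
#> [1] "000110111001"
code <- apply_trait_rules(pat)
code
#> [1] "1111"
trait_name(code)
#> [1] "Complete Denitrification"
```

Every step has a complete complex (napAB, nirS, norBC, nosZ), so the
genome is a complete denitrifier even though six of the twelve genes are
absent.

The curated archaeal records — the 21 Halobacteriota genomes that encode
both nitrite reductases — run through the same dataset machinery:

```r
ds <- archaeal_examples_dataset()
glance(ds)
#>   n_genomes n_enzyme_patterns n_traits n_genera n_complete n_excluded
#> 1        21                 6        2        7          0          0

summarize_dataset(ds, "ecosystem_category")
#>   ecosystem_category n_genomes n_patterns
#> 1 Aquatic                    9          4
#> 2 Fish                       2          1
#> 3 Food production            2          1
#> 4 Terrestrial                8          5

detect_replicate_strains(ds)
#>   genome_name                          n_genomes
#> 1 Halobiforma lacisalsi AJ5, JCM 12983         2
#> 2 Natrinema pellirubrum 157                    2
#> 3 Natrinema thermotolerans A29                 2
```

21 genomes from 7 genera and 18 distinct strains; three strains are
represented by two genome sequences each.

A synthetic cohort exercises the whole pipeline — generated KO lists and
metadata are read back, merged, and rebuilt into a dataset that must match
the planted truth:

```r
spec <- cohort_spec(seed = 7, n_genomes = 500)
g <- generate_cohort(spec, "cohort_dir")
ds <- ingest_cohort("cohort_dir")
glance(ds)
#>   n_genomes n_enzyme_patterns n_traits n_genera n_complete n_excluded
#> 1       500               405        6        8          0          0
```

`plot_trait_distribution(ds)` and `plot_enzyme_prevalence(ds)` chart the
trait and per-gene distributions.

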