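# kgfuse

Entity fusion for disease-centred medical knowledge graphs.

Triples extracted from electronic medical records and from curated health
websites describe the same diseases with different vocabularies: records
are rich in symptom mentions spelled in clinical shorthand, websites carry
standardized entries with examinations, treatments and alternative names.
`kgfuse` aligns and merges the two graphs: it decides which cross-source
entities denote the same concept, rewrites every triple to a canonical
entity, and exports the fused graph. It is aimed at practitioners building
clinical knowledge graphs from heterogeneous sources who need a
reproducible, supervised fusion step — and a synthetic benchmark to
validate it without access to private clinical data.

## Method

Knowledge is modeled as triples (head, relation, tail) under a fixed
disease-centred schema of ten relation signatures (`kg_schema()`), e.g.
`Diseases_rel_Symptom: disease → symptom`. Fusion proceeds in two
supervised stages:

**Tail fusion** (symptoms, examinations — the types present in both
sources). Every cross-source same-type pair is scored by a binary
classifier (logistic regression, decision tree, or a small neural
network) on three features:

* *semantic similarity* — a pluggable scorer, by default the cosine of
  character-bigram count vectors;
* *embedding similarity* — cos(**h₁**, **h₂**) of translational
  knowledge-graph embeddings (TransE / TransH / TransR, trained in-package
  with margin ranking loss `max(0, γ + f(h,r,t) − f(h′,r,t′))` and
  type-constrained negative sampling, where TransR scores
  `f(h,r,t) = ‖h·M_r + r − t·M_r‖`);
* *Jaccard similarity* — `|A∩B| / |A∪B|` over the character sets of the
  two surface forms.

**Head fusion** (diseases). Pairs sharing a normalized name — primary
surface, case-insensitive English name, or a surface matching an
alternative-name attribute — are merged directly. The remainder is scored
by a second classifier on structural features computed over the
already-fused tails: the number of identical canonical tail nodes, the
Jaccard coefficient of the pooled characters of the two tail-surface
sets, and the embedding cosine of the heads.

Accepted pairs (greedy one-to-one above a probability threshold) are
closed under union-find; the fused graph can be annotated with ICD codes
and exported as Neo4j bulk-import CSV or RDF N-Triples. A generator
builds ground-truth benchmarks with two corrupted source views and
exhaustive alignment labels. See the methods vignette
(`vignettes/entity-fusion.Rmd`) for the full model description.

## Worked example

```r
library(kgfuse)

cfg <- pipeline_config(
  generator  = generator_config(seed = 42, n_diseases = 20),
  embedding  = embedding_config("transR", dim = 16, epochs = 50,
                                learning_rate = 0.02, margin = 2, seed = 1),
  log_level = "quiet")
rep <- run_pipeline(cfg, "runs/demo")

cat(sprintf("triples  %d -> %d\n", rep$triples_before, rep$triples_after))
cat(sprintf("entities %d -> %d\n", rep$entities_before, rep$entities_after))
cat(sprintf("tail alignment F1: %.3f   head alignment F1: %.3f\n",
            rep$tail_metrics$f1, rep$head_metrics$f1))
print(unlist(rep$merges_by_stage))
```

```
triples  727 -> 524
entities 262 -> 192
tail alignment F1: 0.990   head alignment F1: 0.974
 attribute      exact head_model tail_model
         1         12          6         51
```

The pipeline simulated a 20-disease ground truth with two corrupted views
(262 entities across both), trained TransR embeddings on their union,
fused tails and heads, and merged 70 entity pairs: 12 diseases by exact
name, 1 by alternative-name attribute, 6 by the structural classifier,
and 51 tails by the feature classifier. Collapsing duplicates shrank the
graph from 727 to 524 triples; the F1 scores measure the merge map
against the generator's ground-truth alignment labels. `runs/demo/`
contains the views, embeddings, merge tables, fused graph, Neo4j CSVs,
N-Triples file, `report.json` and the full provenance `config.yaml`;
rerunning with the same config reproduces every file byte-identically.

The same stages are scriptable from a shell via `exec/kgfuse`
(`simulate`, `embed`, `fuse-tail`, `fuse-head`, `export`, `evaluate`,
`run`).

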