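# cgcqtl

Candidate-gene prioritization and QTL connectivity analysis for
experimentally induced arthritis models (and structurally similar
keyword/QTL studies).

Rat crosses between arthritis-susceptible and resistant strains yield
quantitative trait loci (QTLs) — genomic intervals so broad that they
cover about half the genome. `cgcqtl` implements, as a tested R package,
the three-stage analysis used to ask what that actually buys you:

1. **CGC scoring.** Each gene has a free-text descriptive record
   (emulating OMIM) and each keyword *k* a percentage weight — its
   *relevance index*
   `w_k = 100 · n(k ∧ ref) / n(k)`
   from literature co-occurrence counts against a reference term
   ("arthritis"). A gene's CGC score is `Σ w_k` over the *distinct*
   keywords found in its record (whole-token matching, case-insensitive,
   each keyword counted once).
2. **Genome partition.** Genes with CGC ≥ 0.1 are classified inside /
   outside the flattened QTL union, stratified into score bins
   `[0.1,10), [10,20), …, [200,∞)`, and each bin's split is tested
   against the genome-wide inside proportion (1-df chi-square, no
   continuity correction).
3. **QTL connectivity.** Record hyperlinks become undirected gene–gene
   edges. For QTLs from two different crosses, each cross-cross QTL pair
   is tested for an excess of connecting gene pairs over the expectation
   `T · n1·n2 / Σ n_i·n_j` with a Yates-corrected 2×2 chi-square
   (`N(|ad−bc|−N/2)²/((a+b)(c+d)(a+c)(b+d))`); connecting pairs where at
   least one gene has CGC ≥ 50 are reported as strong candidates.

A seeded generator (`synth_config()`, `simulate_study()`) produces
complete synthetic studies — catalog, QTL table, keywords, record corpus,
links — with controllable inside-QTL keyword enrichment and per-QTL-pair
edge excess, so everything runs without downloads.

## Worked example

```r
library(cgcqtl)

cfg <- synth_config(seed = 7)          # study-scale defaults: 2403 genes,
st  <- simulate_study(cfg)             # 49 keywords, 5+9 QTLs, ~50% coverage

scored <- score_corpus(st$corpus, st$keywords)
report <- partition_report(st$catalog, st$qtls, scored)
report
```

```
CGC score stratification, genes inside vs outside QTL regions

 CGC score within QTLs outside QTLs P (chi2)
     200 -           1            1     0.89
 100 - 200          58           86     0.23
  50 - 100         281          312     0.31
   30 - 50         178          207     0.71
   20 - 30         137          170     0.81
   10 - 20          83          118     0.25
  0.1 - 10         109          129     0.88

Total: 847 within (45%), 1023 outside (55%)
```

With a null text model (no inside-QTL enrichment), every stratum splits
close to the genome-wide 45/55 proportion and no bin p-value is small —
candidate genes are distributed indifferently to QTL boundaries, which is
exactly the situation the method is designed to detect (or refute).

Connectivity, with a planted 5× edge excess between one clean QTL pair:

```r
g  <- generate_genome(cfg)
dp <- designate_clean_pair(g$catalog, g$qtls)     # "QA05|QB02" at seed 7
cfg2 <- synth_config(seed = 7, pair_excess = setNames(list(5), dp$key))
st2 <- simulate_study(cfg2)
gr  <- build_connection_graph(st2$links, st2$catalog, st2$qtls)
head(qtl_pair_results(gr), 3)
```

```
  qtl1  n1 qtl2  n2 observed expected     chi2           p    p_holm        flag
1 QA05 115 QB02 129       48 13.68290 8.273697 0.004022352 0.1810058 significant
2 QA03  97 QB02 129       10 11.54123 4.149590 0.041644602 1.0000000
3 QA02 113 QB02 129       11 13.44494 2.375575 0.123246184 1.0000000
```

The planted pair QA05–QB02 is recovered and flagged (48 observed
connections vs 13.7 expected). The second row shows why flagging is
directional: its raw p is below 0.05 but the pair has a *deficit*
(10 < 11.5), so it is correctly left unflagged.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/cgcqtl simulate --out study --seed 7
Rscript inst/scripts/cgcqtl partition --keywords study/keywords.tsv \
    --catalog study/catalog.tsv --qtls study/qtls.tsv \
    --corpus study/corpus.jsonl --out results
Rscript inst/scripts/cgcqtl connect --config run.dcf --out results
```

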