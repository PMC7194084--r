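# svintegrate

Integration, annotation and visualization of multi-caller structural
variant (SV) predictions in R.

## The problem

Short-read SV callers disagree with each other: read-pair, split-read
and read-depth signals each miss different event classes, and no single
caller is a gold standard. The standard remedy is to run several
callers and keep only the predictions they agree on. That requires (1)
parsing seven mutually incompatible output dialects, (2) filtering each
caller's low-quality predictions, (3) deciding when two predictions
describe *the same* SV, and (4) making the consensus set usable —
annotated against gene models and visualized along the genome.
`svintegrate` does all four for BreakDancer, Pindel, CNVnator, DELLY,
SVseq2, Lumpy and SoftSearch, for deletions (del), duplications (dup)
and inversions (inv).

## The method

Two same-type predictions *a*, *b* on one chromosome are concordant
when their **reciprocal overlap**

```
RO(a, b) = min( |a ∩ b| / |a|,  |a ∩ b| / |b| )
```

strictly exceeds a threshold (default 0.8). Pairwise distances are set
to 0 when RO > 0.8 and 1 otherwise; single-linkage hierarchical
clustering of this 0/1 matrix — equivalently, connected components of
the overlap graph, which is how the default code path computes it —
partitions the combined predictions into clusters. A cluster supported
by ≥ 2 distinct callers becomes one unified SV whose `pos1`/`pos2` are
the (rounded) means of the member breakpoints; clusters supported by a
single caller are discarded.

Before merging, each reader applies its caller's quality gates:
BreakDancer score ≥ 60 and ≥ 3 discordant read pairs; Pindel and SVseq2
≥ 3 split reads; SoftSearch ≥ 3 split reads **and** ≥ 3 discordant
pairs; DELLY PE + SR ≥ 3; Lumpy SU ≥ 3; and, for every caller, an
effective size (|reported size|, falling back to the coordinate span)
within [100 bp, 10 Mb]. All thresholds live in a single
[`merge_params()`] object and can come from a `key = value` config
file.

## Worked example

No external data is needed: the package ships a benchmark simulator
that plants ground-truth SVs and writes them in every caller dialect,
with boundary jitter and caller-unique false positives.

```r
library(svintegrate)

spec  <- genome_spec()                       # 5 chromosomes x 20 Mb
truth <- simulate_truth(spec, n_per_type = c(del = 30, dup = 12, inv = 8),
                        seed = 42)
dir   <- file.path(tempdir(), "svdemo")
res   <- emit_caller_outputs(truth, spec,
           callers = c("breakdancer", "pindel", "cnvnator", "delly", "lumpy"),
           jitter_frac = 0.05, fp_per_caller = 10, out_dir = dir, seed = 43)

breakdancer <- read_breakdancer(file.path(dir, "breakdancer.txt"))
breakdancer
#> CallSet: BreakDancer
#>   del: 33 records
#>   inv: 11 records
str(breakdancer$del[1:3, ])
#> 'data.frame':	3 obs. of  5 variables:
#>  $ chromosome: chr  "chr01" "chr01" "chr01"
#>  $ pos1      : int  4817419 6517906 7443038
#>  $ pos2      : int  4875762 6526679 7455635
#>  $ size      : num  58344 8774 12598
#>  $ info      : chr  "score=90;PE=24" "score=70;PE=4" "score=72;PE=19"

css    <- read_simulated(dir, c("breakdancer", "pindel", "cnvnator",
                                "delly", "lumpy"))
css    <- lapply(css, resolve_self_overlaps)
merged <- methods_merge(css)
merged
#> MergedSVList
#>   del: 30 merged SVs
#>   dup: 12 merged SVs
#>   inv: 8 merged SVs
head(merged$del[, 1:4], 3)
#>   chromosome    pos1    pos2                                 methods
#> 1      chr01 4817798 4877615 BreakDancer:Pindel:CNVnator:Delly:Lumpy
#> 2      chr01 6517742 6526568 BreakDancer:Pindel:CNVnator:Delly:Lumpy
#> 3      chr01 7442838 7455627                       BreakDancer:Lumpy

ev <- evaluate_against_truth(merged, res$manifest)
sprintf("precision = %.3f, recall = %.3f, mean boundary error = %.1f bp",
        ev$precision, ev$recall, ev$mean_boundary_error)
#> "precision = 1.000, recall = 1.000, mean boundary error = 153.5 bp"
```

Every planted SV reported by ≥ 2 callers is recovered (recall 1), every
caller-unique false positive forms a one-method cluster and is
discarded (precision 1), and the consensus breakpoints sit within the
injected 5% jitter of the truth. The `methods` column names the
contributing callers, first-appearance ordered; `info` concatenates
their support strings in the same order.

Downstream:

```r
elements <- read_gene_models("genes.gff3")          # introns derived,
ann      <- annotate_svs(merged, elements)          # 2 kb flanks tagged
count_affected_genes(ann)                           # distinct genes per type
wc <- window_counts(merged, spec$chromosomes, window = 1e6)
plot_genome(wc, style = "circular", out = "genome.png")
plot_region(merged, elements, "chr01:6400000-6700000", out = "region.png")
```

## Command line

The same pipeline is scriptable via
`Rscript inst/cli/svintegrate.R <verb> [--flags]` (or
`svintegrate::run_cli()`), with verbs `simulate`, `read`, `merge`,
`annotate`, `plot-genome`, `plot-region`, `evaluate` and `run-all`.
Exit codes: 0 success, 2 configuration error, 1 data error.

```sh
Rscript inst/cli/svintegrate.R run-all --out-dir demo --seed 3 \
    --fp-per-caller 50
```

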