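# brxrscan

Comparative-genomics toolkit for locating **BrxR-family (WYL-domain)
transcriptional regulators** in annotated bacterial genomes and
characterising the phage defence islands they sit in, plus quantification
of the EMSA experiments used to validate their operator binding.

BrxR-type regulators are winged-HTH/WYL proteins that repress phage
defence operons (BREX, restriction–modification, CRISPR-Cas, CBASS,
toxin–antitoxin systems, ...) and typically sit at the edge of the
defence island they control, binding an operator of two ~11-bp inverted
repeats ("R-BOX"). The package is for microbial genomicists who want to
run this guilt-by-association analysis on their own genome sets, and for
biochemists quantifying regulator–operator binding from gel shift data.

## What it computes

* **Protein homology search** — exact Smith–Waterman/Gotoh local
  alignment (BLOSUM62, affine gaps 11/1, no heuristic seeding) with
  Karlin–Altschul statistics: `E = K · m′ · n′ · e^(−λS)` (gapped
  λ = 0.267, K = 0.041). Hits retained at `E < 1e-5` (primary) or
  `1e-3` (sensitivity). External 12-column tabular results can be
  ingested instead for full-scale runs.
* **Neighbourhood association** — each regulator locus is scanned for
  defence-marker hits within a strand-aware window of W = 50 kb
  downstream and upstream (edge-gap distances); marker hits of one
  system within 20 kb collapse to a system instance; loci are classified
  `downstream_only / upstream_only / both / none`, and summarised by
  system class, class co-occurrence (UpSet-style counts), taxonomy and
  chromosome/plasmid location.
* **Inverted-repeat discovery** — all maximal mismatch-tolerant inverted
  repeats (arm ≥ 20 bp, spacer < 8 bp, ≤ 2 mismatches by default) in up
  to 200 bp upstream of each locus; exact, oracle-checked semantics.
* **EMSA quantification** — fractional saturation `Y = 1 − I_T / I_C`
  from unbound-band intensities, and the dissociation constant from
  nonlinear least squares on the binding isotherm
  `Y(c) = Ymax · c / (Kd + c)` (optional Hill exponent).
* **Synthetic data** — deterministic generators for annotated genomes
  with planted regulators / defence systems / decoys / upstream inverted
  repeats and machine-readable truth tables, plus binding-curve and
  lineage generators. Every analysis stage is validated against these
  truths and against independent brute-force oracles.

## Worked example

```r
library(brxrscan)

# 6 synthetic genomes with planted islands straddling the 50-kb window
corp <- simulate_corpus(n_genomes = 6, seed = 42, out_dir = "demo")

cfg <- pipeline_config(genomes_dir = "demo/genomes",
                       query       = "demo/query.faa",
                       panel_fasta = "demo/panel.faa",
                       panel_tsv   = "demo/panel.tsv",
                       lineage     = "demo/lineage.tsv",
                       out_dir     = "demo/out")
res <- run_scan(cfg)
#> searching regulator query against 6 genome(s)
#> regulator hits passing E < 1e-05: 7
#> marker hits passing E < 1e-05: 11
#> anchored loci: 7 (from 7 hits)
#> associated loci (any direction): 4 of 7
#> inverted repeats: 4 in 3 of 7 loci

res$records
#>         locus_id     W n_downstream n_upstream         verdict
#> 1 synthg001:reg1 50000            0          0            none
#> 2 synthg002:reg1 50000            1          0 downstream_only
#> 3 synthg003:reg1 50000            1          1            both
#> 4 synthg004:reg1 50000            0          0            none
#> 5 synthg005:reg1 50000            0          1   upstream_only
#> 6 synthg006:reg1 50000            1          0 downstream_only
#> 7 synthg006:reg2 50000            0          0            none
```

Seven regulator loci are found in six genomes (one genome carries two).
Four loci have at least one defence system within 50 kb
(`res$summary$pct_assoc_any` = 57.14%); `synthg003:reg1` has systems on
both sides — its downstream instance sits at exactly 49,500 bp and its
upstream one at exactly 50,000 bp, both inside the window, while
`synthg004:reg1`'s planted system at 50,001 bp is correctly excluded.
All detailed tables (`loci.tsv`, `instances.tsv`, `cooccurrence.tsv`,
`class_distribution.tsv`, `taxonomy.tsv`, `inverted_repeats.tsv`, ...)
plus a `manifest.json` with the configuration hash are in `demo/out/`.

Binding quantification:

```r
cv <- generate_binding_data(kd = 13, ymax = 1,
                            concs = 10^seq(0, log10(400), length.out = 8),
                            sigma = 0.03, replicates = 3, seed = 11)
fit_kd(cv)
#> Kd = 13.5 +/- 0.608 nM (ymax 0.994, n 1.00, hyperbolic, 24 points)
```

The fitted Kd (13.5 nM) recovers the generating constant (13 nM) within
the noise; the standard error comes from the covariance of the fit.

A command-line interface wraps the same stages:

```sh
Rscript -e 'brxrscan::cli_main()' simulate --n 6 --seed 42 --out demo
Rscript -e 'brxrscan::cli_main()' ir --in probes.fna --out ir.tsv --min_arm 11
Rscript -e 'brxrscan::cli_main()' emsa-fit --in emsa.tsv --out estimates.tsv
```

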