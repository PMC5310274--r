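# rnnbias

Sequence-specific bias correction for RNA-seq read counts using
character-level recurrent neural network language models.

## What it does, and for whom

Random-primer binding during cDNA synthesis prefers some nucleotide
contexts over others, so RNA-seq read 5'-ends are not placed uniformly
within transcripts: the probability that a read starts at a position
depends on the sequence around it. For anyone estimating gene expression
from read counts, this *sequence-specific bias* distorts FPKM values in a
gene-composition-dependent way.

`rnnbias` implements the correction pipeline end to end:

1. **Count** uniquely mapped read 5'-ends at each exonic position
   (SAM or a simple read-start TSV; genome from FASTA, gene models from
   BED12).
2. **Sample** *foreground* context windows (21 bp centred on observed read
   starts, weighted by read count) and *background* windows (same sites
   randomly offset by up to ±30 bp), split 90:5:5 into
   train/validation/test.
3. **Train** a pair of nucleotide language models — vanilla RNN, GRU, or
   LSTM, implemented from scratch with backpropagation through time — that
   assign each window a probability via the chain rule
   `p(S) = p(s_1) · prod_t p(s_t | s_1..s_{t-1})`, with per-symbol
   conditionals `softmax(V h_t + c)` over the hidden state of the
   recurrent unit.
4. **Weight** every counted site by `bias = p_fg(window) / p_bg(window)`.
5. **Quantify** gene expression as FPKM, dividing each position's count by
   its bias weight: `1e9 · Σ_i n_i / bias_i / (length(gene) · N_total)`.
6. **Evaluate** with log-Pearson correlation, Spearman correlation, r²
   (the squared log-Pearson), and before/after shift diagnostics.

A synthetic-data simulator with a *known* injected positional-weight-matrix
bias makes every stage testable without external downloads, and a model
selection rule (minimum validation next-symbol error rate) keeps the
lightweight models (10–20 hidden units; a GRU-10 has exactly 524
parameters, an LSTM-20 has 2164) honest.

## Worked example

Simulate a dataset with a strong known bias (±ln 3 log-weights at the five
central window positions), train a GRU-10 foreground/background pair, and
compare raw and corrected FPKM against the simulated truth:

```r
library(rnnbias)

sim    <- simulate_dataset(sim_config(pwm = example_bias_pwm(10), seed = 1))
counts <- count_read_starts(sim$sites, sim$gene_models)
counts
#> 13717 exonic read-start site(s), 50000 mapped reads

fg <- sample_foreground_sites(counts, 3000, seed = 2)
bg <- sample_background_sites(fg, max_offset = 30, genome = sim$genome,
                              seed = 3, w = 10)
fg_ds <- split_dataset(extract_context_sequences(fg, sim$genome, 10,
                                                 "foreground")$seq, seed = 4)
bg_ds <- split_dataset(extract_context_sequences(bg, sim$genome, 10,
                                                 "background")$seq, seed = 5)

fg_model <- train_model(rnn_spec("gru", 10), fg_ds,
                        train_config(epochs = 12, learning_rate = 3e-3, seed = 6))
fg_model
#> GRU(4-10-4) language model: 524 parameters, 12 epoch(s) trained, checkpoint 10 selected
#>   validation NLL 1.3785 nats/symbol, error rate 0.7111
bg_model <- train_model(rnn_spec("gru", 10), bg_ds,
                        train_config(epochs = 12, learning_rate = 3e-3, seed = 7))

cat(sprintf("fg test perplexity: %.3f  bg test perplexity: %.3f\n",
            perplexity(fg_model, fg_ds$test), perplexity(bg_model, bg_ds$test)))
#> fg test perplexity: 3.978  bg test perplexity: 4.000

bias <- build_bias_table(fg_model, bg_model, sim$genome, counts, w = 10)
expr <- quantify(counts, sim$gene_models, bias)

truth <- sim$truth$genes$abundance
for (kind in c("raw", "corrected")) {
  m <- correlation_metrics(expr[[paste0(kind, "_fpkm")]], truth)
  cat(sprintf("%-9s spearman %.4f  log-pearson %.4f  r2 %.4f\n",
              kind, m$spearman, m$pearson_log, m$r2))
}
#> raw       spearman 0.9847  log-pearson 0.9882  r2 0.9766
#> corrected spearman 0.9927  log-pearson 0.9952  r2 0.9904

sh <- expression_shift(expr$raw_fpkm, expr$corrected_fpkm)
cat(sprintf("shift: rms log10 fold %.4f, %d genes up, %d genes down\n",
            sh$euclidean, sh$n_increased, sh$n_decreased))
#> shift: rms log10 fold 0.0470, 54 genes up, 46 genes down
```

The corrected estimates track the simulated truth more closely on every
metric; with no injected bias (`pwm = NULL`) the same pipeline is a
near-no-op (RMS log10 fold change ≈ 0.01).

## Command line

A thin wrapper over the same functions is installed as `exec/rnnbias`:

```sh
rnnbias=$(Rscript -e 'cat(file.path(find.package("rnnbias"), "exec", "rnnbias"))')
Rscript "$rnnbias" simulate --out-dir sim --seed 1 --bias strong
Rscript "$rnnbias" sample   --genome sim/genome.fa --genes sim/genes.bed \
                            --reads sim/reads.tsv --out-dir samp --n 3000 --seed 1
Rscript "$rnnbias" train    --train samp/fg_train.txt --validation samp/fg_validation.txt \
                            --unit gru --hidden 10 --out fg.json --seed 1
# ... bias / quantify / evaluate; see `Rscript "$rnnbias" --help`
```

Every subcommand takes `--seed` and writes all artifacts to disk; identical
arguments and seed reproduce byte-identical outputs.

## Vignette

`vignettes/bias-correction-methods.Rmd` documents the model and its
assumptions, the training and model-selection procedure, the numerical
conventions, what the simulator does and does not emulate, and known
limitations.
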