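# marginattn

Margin-optimized attention for binary motor-imagery EEG decoding.

## The problem

Motor-imagery brain-computer interfaces classify EEG recorded while a
person imagines moving the left or right hand. The discriminative signal
is event-related desynchronization (ERD): imagining a hand movement
attenuates mu-band (8-12 Hz) power over the contralateral sensorimotor
cortex. The signal is weak, noisy and overlaps heavily between classes, so
decoders need feature extractors that actively separate the classes, not
just describe the input.

`marginattn` implements a decoding pipeline in which the attention layer is
itself a margin classifier. Conventional scaled dot-product attention
weights key positions by feature similarity:

    Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V

Here the scores are instead an affine function `s_j = A . phi(x_j) + b` of
the encoder features, and `(A, b)` are trained under the soft-margin SVM
objective through its differentiable hinge surrogate

    L_SVM = 1/2 ||A||^2 + C * sum_i max(0, 1 - y_i (A . phi(x_i) + b)),

which joins the cross-entropy loss in ordinary backpropagation (no
quadratic-programming solver at run time). The normalized margin scores
replace the softmax similarity scores and modulate the values, so attention
is both context-aware and class-discriminative; at inference no labels are
needed and the auxiliary term is simply absent.

Around that core the package provides:

* **Synthetic EEG** (`synth_config`, `generate_dataset`): multi-subject
  cue-locked recordings with lateralized mu-band ERD, 1/f background
  noise, sub-4-Hz blink transients, and between-subject variability —
  every stage of the pipeline is testable without downloading a dataset.
* **Preprocessing** (`filter_spec`, `highpass_filter`, `segment_epochs`,
  `reject_trials`, `reject_channels`): 4th-order Butterworth high-pass at
  4 Hz, 4-s cue-locked epochs, and mean-absolute-value rejection of trials
  and channels beyond mean + 3 SD.
* **Backbone** (`backbone_config`, `build_backbone`, `shape_trace`): a
  channels-as-depth CNN (EEG channels as convolutional depth, algebraic
  depth progression, (1, k) kernels with stride-2 ceiling-halving of the
  time axis) feeding a many-to-one bidirectional LSTM and a dense head,
  with selectable attention (`none`, learned-score `softmax`,
  `multi_head`, `svm_margin`) and the experimental `|x| tanh(x)` head
  activation.
* **Transformer variant** (`transformer_config`, `build_transformer`,
  `crop_series`, `patch_encode`): 45-sample crops resized to 72, patch
  embedding with positional encodings, pre-norm encoder blocks
  (LN -> attention -> skip, LN -> MLP -> skip), AdamW with metric-based
  early stopping; margin attention is a drop-in replacement for multi-head
  attention inside the block.
* **Evaluation harness** (`loso_folds`, `run_loso`, `run_ablation`,
  `classification_metrics`, `class_separation`, `one_way_anova`,
  `attention_heatmap`): leave-one-subject-out protocol, accuracy / F1 /
  sensitivity, Fisher class-separation of pooled features, one-way ANOVA
  across models, and PNG attention heatmaps.

All networks run on a compact reverse-mode autodiff engine over base-R
arrays that ships with the package; its gradients are verified against
central finite differences in the test suite.

## Worked example

```r
library(marginattn)

# 4 subjects of cue-locked motor imagery at 90 Hz with 50% mu-power ERD
cfg <- synth_config(n_subjects = 4, n_trials_per_subject = 120,
                    erd_factor = 0.5, seed = 1)
recs <- generate_dataset(cfg)
eps  <- prepare_dataset(recs)        # filter -> epoch -> reject -> 180 samples

res <- run_loso(eps, variant = "svm_margin", seed = 1)
res$per_fold
#>   subject  accuracy        f1 sensitivity class_separation n_test
#> 1       1 0.7142857 0.7166667   0.7166667        0.6180929    119
#> 2       2 0.7250000 0.7027027   0.6500000        0.5650897    120
#> 3       3 0.8333333 0.8360656   0.8500000        1.0349206    120
#> 4       4 0.7916667 0.7967480   0.8166667        0.8216616    120
round(res$pooled$accuracy, 3)
#> [1] 0.766
```

Each row is one leave-one-subject-out fold: the model is trained on the
other three subjects and tested on trials of the held-out subject it has
never seen (119 trials for subject 1 because one artifact trial was
rejected). `class_separation` is the Fisher criterion
`J = ||mu_+ - mu_-||^2 / (tr(Sigma_+) + tr(Sigma_-))` of the
attention-pooled feature vectors: larger means the two imagery classes
occupy better-separated regions of the learned feature space. Accuracies
around 0.7-0.8 at this small training-set size (three subjects) reflect
the between-subject variability the LOSO protocol is meant to expose;
with more training subjects the same pipeline scores in the high 0.9s on
this generator.

The printed shape arithmetic of the reference channels-as-depth
configuration (64 channels, 180-sample window):

```r
shape_trace(backbone_config(64, n_layers = 6, depth_start_multiplier = 2,
                            input_time = 180))
#>   layer batch depth spatial time flattened
#> 1     1     1   128       1   90     11520
#> 2     2     1   192       1   45      8640
#> 3     3     1   256       1   23      5888
#> 4     4     1   320       1   12      3840
#> 5     5     1   384       1    6      2304
#> 6     6     1   448       1    3      1344
```

versus 49,152 flattened features (and 16,384 per LSTM step instead of 448)
when the 64-channel spatial axis is preserved — the computational argument
for treating channels as depth.

## Command line

A thin CLI over the package functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/marginattn", package="marginattn"))') \
    simulate --subjects 4 --trials 100 --erd 0.5 --seed 1 --out sim/
# then: preprocess / train / evaluate / ablate   (see --help of each)
```

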