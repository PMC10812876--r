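# oudel

Predicting whether genes lost by deletion were functionally **redundant**
or **unique**, from expression data, under an Ornstein–Uhlenbeck (OU) model
of expression evolution.

## The problem

After a gene duplication in the common ancestor of two sister species, a
later deletion can remove one copy in one lineage.  Three genes remain
measurable: the surviving copy in the deletion-bearing species (**D**,
derived), its ortholog in the second species (**S**, survived), and the
copy still present in the second species but lost in the first (**L**,
lost).  Expression evolves toward optima under selection (strength
$\alpha$) and drifts (rate $\sigma^2$): D and S share optimum $\theta_1$,
while L and the pre-duplication ancestor hold $\theta_2$.  A deletion event
is *redundant* when $\theta_1 = \theta_2$ in every measured condition and
*unique* otherwise.  Per condition, expression of (D, S, L) is trivariate
normal with

$$\mu = \big(w\theta_2 + (1{-}w)\theta_1,\; w\theta_2 + (1{-}w)\theta_1,\; \theta_2\big),\quad w = e^{-\alpha T_{DS}},$$

$$\Sigma = \tfrac{\sigma^2}{2\alpha}\begin{pmatrix}1 & e^{-2\alpha T_{DS}} & e^{-2\alpha}\\ e^{-2\alpha T_{DS}} & 1 & e^{-2\alpha}\\ e^{-2\alpha} & e^{-2\alpha} & 1\end{pmatrix},$$

with the duplication time scaled to 1 and $T_{DS}$ the D–S divergence
time.  `oudel` simulates labelled deletion events from this model
(rejection-sampled against empirical expression bounds), trains four
supervised predictors — a feed-forward neural network, gradient-boosted
trees, a random forest and a radial-basis SVM — to classify events and to
regress $\theta_1$, $\theta_2$ and the log stationary variance
$\log_{10}\sigma^2/(2\alpha)$ per condition, and provides a classical
maximum-likelihood / likelihood-ratio-test baseline plus ROC / power /
confusion / parameter-error evaluation tooling.  It is aimed at
comparative genomicists with multi-condition expression tables for
deletion events in a two-species system.

## A worked example

```r
library(oudel)

# 2,000 labelled events, 6 conditions, the broad evolutionary prior
train <- simulate_deletion_data(sim_config(n_events = 2000), seed = 1)
test  <- simulate_deletion_data(sim_config(n_events = 500),  seed = 2)
train
#> <oudel_sim> 2000 events, m = 6 conditions (standard scenario)
#> # A tibble: 2 × 2
#>   class         n
#>   <chr>     <int>
#> 1 redundant  1000
#> 2 unique     1000

fit <- train_deletion_classifier(train, "rf", seed = 3)
conf <- confusion_accuracy(predict(fit, test), test$data$class)
round(conf$accuracy, 3)
#> [1] 0.942

curve <- roc_curve(predict(fit, test, type = "prob")[, "unique"],
                   test$data$class)
round(c(auc = roc_auc(curve), power5 = power_at_fpr(curve, 0.05)), 3)
#>    auc power5
#>  0.984  0.936
```

The accuracy is the fraction of held-out events whose redundant/unique
call matches the generating truth; `power5` is the true-positive rate for
detecting unique events when the threshold is set so that at most 5% of
redundant events are miscalled.  A regressor for the evolutionary
parameters and the LRT baseline work the same way:

```r
reg <- train_deletion_regressor(train, "rf", seed = 4)
errs <- error_distributions(predict(reg, test, type = "params"), test)
dplyr::summarise(dplyr::group_by(errs, output),
                 median_error = median(error))
#> # A tibble: 3 × 2
#>   output  median_error
#>   <chr>          <dbl>
#> 1 log10sv     -0.115
#> 2 theta1      -0.00751
#> 3 theta2      -0.00573

lrt_panel(test$data[1:3, ], lrt_config(n_starts = 5), seed = 5)[, 1:7]
#> # A tibble: 3 × 7
#>   event_id ll_null ll_alt statistic p_value score label
#>   <chr>      <dbl>  <dbl>     <dbl>   <dbl> <dbl> <chr>
#> 1 ev00477   -20.2  -18.1      4.06   0.0439 0.956 unique
#> 2 ev00037    -8.41  -8.30     0.223  0.637  0.363 redundant
#> 3 ev00251   -28.3  -27.2      2.11   0.147  0.853 redundant
```

Empirical tables (tab-separated: `event_id`, `lineage`, `gene_D`,
`gene_S`, `gene_L`, then `eD_1 ... eL_m` log-normalised expression) are
read with `read_empirical_table()`, scored with
`class_and_param_summary()`, and checked for model consistency with
`back_simulate_check()`.  A thin command-line wrapper (`exec/oudel`)
exposes `simulate | train | predict | lrt | evaluate | noise-test |
empirical`.

See the methods vignette (`vignettes/oudel-methods.Rmd`) for the model,
the training protocols, numerical choices and known limitations.

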