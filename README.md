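# treevigor

Joint individual-based modelling of tropical tree growth and mortality,
coupled through **tree vigor** — the individual residual of a trait-based
growth model.

## The problem

In closed tropical forests, trees that grow less than expected for their
species and size are the trees most likely to die. Forest demographic
models usually fit growth and mortality separately, which both discards
that early-warning signal and double-counts covariates that act on
mortality *through* growth. `treevigor` implements a coherent alternative
for decadal census data: a nonlinear growth model and a logistic mortality
model are inferred **simultaneously** from one joint likelihood, linked by
a per-tree, per-interval vigor covariate. It is aimed at forest ecologists
and modellers working with repeated diameter inventories plus species-level
functional traits.

## The model

Growth, on the scale `y = log(AGR + 1)` (AGR in mm/yr), follows a
hump-shaped ontogenetic trajectory:

```
y[i,t] = Gmax_s * exp( -1/2 * ( log(D[i,t-1] / (theta5 * DBH95_s)) / (theta6 * WD_s) )^2 ) + eps,
Gmax_s = theta1*DBH95_s + theta2*WD_s + theta3*Hmax_s + theta4*d13C_s,
eps ~ N(0, sigma^2)
```

Mortality per census interval is logistic in the ontogenetic stage
`x = D/DBH95_s`, four functional traits, and the **vigor** of the previous
interval, `v = y_observed - y_expected`:

```
logit p[i,t] = beta0*v[i,t] + beta1*x + beta2/x
               + beta3*Hmax_s + beta4*Ortho_s + beta5*WD_s + beta6*Tough_s
```

A survivor contributes `prod_t f(D_t | D_{t-1}) (1 - p_t)` to the
likelihood; a tree dying in interval `k` contributes the same factors up to
`k-1` times `p_k`. Inference is componentwise random-walk
Metropolis–Hastings with a conjugate inverse-gamma Gibbs step for
`sigma^2`, and Kuo–Mallick indicator selection over the eight candidate
trait predictors. Because the field data behind the reference analysis are
not distributed, the package ships a forward census simulator
(`simulate_census()`) so the whole chain is validated by parameter
recovery on communities generated from known parameters.

## Worked example

```r
library(treevigor)
sim <- simulate_census(sim_config(n_trees = 3000, n_species = 150, seed = 7))
fit <- tv_fit(sim$census, sim$traits,
              config = mcmc_config(n_chains = 1, n_iter_phase1 = 800,
                                   n_iter_phase2 = 1200, burn_in = 400,
                                   thinning = 5),
              seed = 11)
summary(fit)
```

```
Posterior summary (median and 90% credibility interval):
 parameter   median      q05      q95
    theta1  2.42000  2.36400  2.48300
    theta2 -0.32230 -0.38740 -0.26850
    theta5  0.71770  0.66620  0.78620
    theta6  4.67000  4.40600  4.93300
     sigma  0.50060  0.49320  0.51200
     beta0 -0.34410 -0.58970 -0.10730
     beta5 -0.94620 -1.28600 -0.53460
     beta6 -0.32550 -0.35150 -0.30360
     ...
```

The community was generated with `theta1 = 2.43`, `theta5 = 0.767`,
`sigma = 0.5`, `beta0 = -0.403`, `beta5 = -0.951`, `beta6 = -0.327`: the
posterior medians land on the generating values within their credibility
intervals. The negative `beta0` says a tree growing one log-unit more than
expected has about `exp(-0.34) ≈ 0.71` times the odds of dying.

```r
pseudo_r2(fit)            # 0.243: mortality information gain over the null
cal <- vigor_calibration(fit, seed = 2)
plot(cal)                 # observed vs predicted rate per vigor bin
head(round(as.data.frame(cal), 3), 3)
```

```
  bin mean_vigor observed predicted  lo90  hi90
1   1     -0.876    0.145     0.143 0.111 0.171
2   2     -0.527    0.111     0.120 0.089 0.149
3   3     -0.342    0.119     0.111 0.085 0.140
```

Death rates fall from ~14% per decade in the lowest-vigor tenth to ~5% in
the highest — the vigor effect the model is built around. `residuals(fit)`
returns the per-tree vigor series, `predict(fit)` per-interval death
probabilities, `simulate(fit)` a new census from the fitted posterior
medians, and `tv_fit(..., select = TRUE)` adds Kuo–Mallick predictor
selection (`fit$inclusion` holds the posterior inclusion frequencies).

A thin command-line front end with `simulate`, `fit`, `select`, `evaluate`
and `calibrate` subcommands lives at `inst/scripts/treevigor`.

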