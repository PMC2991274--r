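# fuzzylis

A fuzzy-logic re-reading of the Murray lung injury score.

The Murray score grades acute lung injury by averaging four component
scores, each obtained by banding a physiological variable with hard
cut-offs: the PaO2/FiO2 ratio, respiratory-system compliance, PEEP and the
number of consolidated quadrants on the chest film. Working intensivists do
not reason in hard cut-offs — their categories ("low", "moderate",
"severe") have fuzzy frontiers, and their diagnoses weight the variables
unequally. `fuzzylis` turns a two-questionnaire physician survey into a
weighted Sugeno fuzzy inference system (FIS) that captures this collective
clinical judgement, and quantifies how it departs from the linear Murray
equation. It is aimed at biostatisticians and clinical-decision modellers
working on severity scoring for ALI/ARDS.

## The model

**Crisp reference.** Each variable is banded to a component score 0–4; the
Murray score is the mean of the four components, mapped to a severity level
by `[0, 0.1] -> 0` (no injury), `(0.1, 1.5] -> 1` (mild), `(1.5, 2.5] -> 2`
(moderate, i.e. ALI) and `(2.5, Inf) -> 3` (ARDS).

**Fuzzy system.** From questionnaire 1, where each of P physicians
partitions a variable's segmented range into three contiguous categories,
the package computes *vote densities* — at each segment, the fraction of
the panel assigning it to a category — and fits a parametric membership
function `mu(x)` to each density by least squares over nine families
(Z-shape, S-shape, sigmoid, difference/product of sigmoids, generalized
bell, Gaussian, two-sided Gaussian, trapezoid). The chest film gets five
generalized-bell memberships centered at 0–4 quadrants. From questionnaire
2, where each physician ticks one severity level per antecedent line, every
chosen (line, level) cell becomes a rule

> IF pf is A AND compliance is B AND peep is C AND film is D THEN severity = k,

weighted `w = ticks / P`. For a patient quadruplet `x`, rule `i` fires with
strength `f_i = prod of its four membership degrees` (product T-norm;
`probor(a, b) = a + b - ab` is the declared OR), and the defuzzified degree
of severity is the weighted mean

```
S*(x) = sum_i f_i w_i k_i / sum_i f_i w_i ,
```

rounded to the nearest level in 0–3 (ties upward). Agreement with the crisp
score over a factorial grid of hypothetical patients is summarised by the
S−M difference histogram, the 4×4 contingency table, Cohen's kappa (overall
and ARDS-versus-rest) and a band-wise discrepancy analysis with pooled
two-proportion z-tests.

Because the original raw survey was never published, the package ships a
synthetic-panel simulator (`simulate_survey()`) with configurable frontier
jitter and diagnostic weighting: a `"faithful"` preset that reproduces the
crisp Murray reading, and an `"overweight"` preset in which gas exchange
and consolidations dominate the diagnosis, emulating the nonlinear
behavior reported for the real panel.

## Worked example

```r
library(fuzzylis)

survey <- simulate_survey(behavior = behavior_model("overweight"), seed = 3)
fis <- fis_fit(survey)
fis
#> <sugeno_fis> panel of 12, 224 rules over 135 antecedent lines
#>   fitted memberships:
#>     pf         severe                 zmf       SSE 6.93e-33
#>     pf         moderate               psigmf    SSE 5.91e-04
#>     pf         normal                 smf       SSE 1.73e-33
#>     ...
```

The jittered panel splits its votes, so 135 antecedent lines yield 224
weighted rules and smooth, overlapping membership functions. Grading one
hypothetical patient (PaO2/FiO2 250, compliance 55 ml/cmH2O, PEEP 8 cmH2O,
one consolidated quadrant):

```r
q <- data.frame(pf = 250, compliance = 55, peep = 8, film = 1)
predict(fis, q)
#>      score level
#> 1 1.825951     2
murray_level(murray_score(q))   # crisp Murray: score 1.25 -> level 1
#> [1] 1
```

The simulated panel calls this patient *moderate* (ALI) where Murray's
equation says *mild* — one level of overestimation, the signature
phenomenon this system measures. Over the whole retained evaluation grid:

```r
grid <- apply_exclusions(quadruplet_grid(murray_value_lists()))
S <- predict(fis, grid, type = "level")
M <- murray_level(murray_score(grid))
severity_agreement(S, M)
#> agreement 74.2%, one-level overestimation 17.3%
#> overall: Cohen's kappa 0.5957 ...
```

The published reference table (the original 12-physician study, n =
18,013) is shipped as a plain-text fixture:

```r
cohen_kappa(reference_table())
#> Cohen's kappa 0.1572 +/- 0.0051 (SE), 95% CI 0.1472 - 0.1672
#>   observed agreement 0.4506, chance agreement 0.3481, n = 18013
```

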