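---
title: "Degree-based indices, QSPR models and MCDM ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based indices, QSPR models and MCDM ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqspr)
```

# The analysis this package implements

`topoqspr` is a complete, tested reimplementation of a three-stage
cheminformatics analysis of 22 drugs used against dry eye disease:

1. **Structure → descriptors.** Each drug is modelled as a
   hydrogen-suppressed molecular graph (heavy atoms as vertices, bonds as
   edges, bond order ignored). Eleven degree-based topological indices —
   first and second Zagreb ($M_1$, $M_2$), harmonic ($H$), hyper-Zagreb
   ($HM$), forgotten ($F$), atom-bond connectivity ($ABC$), Randić ($R$),
   sum-connectivity ($SC$), geometric–arithmetic ($GA$), Sombor ($SO$) and
   Nirmala ($N$) — summarise each graph. Every one of them is a sum over
   edges $uv$ of a function of the endpoint degrees $(d_u, d_v)$, so the
   *edge partition* (the count $n_{a,b}$ of edges with endpoint degrees
   $(a,b)$) is a sufficient statistic, and all indices are inner products of
   the count vector with fixed weight vectors.
2. **Descriptors → properties (QSPR).** Seven physicochemical properties
   (boiling point, molar refractivity, polarizability, molar volume,
   enthalpy of vaporization, complexity, molecular weight) are screened
   against the indices by Pearson correlation and regressed on them by
   enter-method multiple linear regression — ordinary least squares with all
   chosen regressors entered simultaneously, no stepwise selection.
3. **Properties → ranking (MCDM).** The drugs are ranked by TOPSIS
   (closeness $C_i = D_i^-/(D_i^+ + D_i^-)$ to ideal/anti-ideal points after
   weighted vector normalisation) and VIKOR (group utility $S_j$, individual
   regret $R_j$, compromise score $Q_j$), all criteria beneficial.

The study data — the property table, the index table, the seven fitted model
summaries and the predicted-value table — ship as plain-text fixtures, and
the packaged values are reproduced *verbatim*, anomalies included. The
guiding principle is **paper-as-data**: the packaged tables are the exact
published cells, validation *reports* inconsistencies, and nothing is
silently corrected.

# The worked example and the edge partition

The one structure worked out in full in the source study is Diclofenac
(C14H11Cl2NO2, 19 heavy atoms, 20 bonds), with edge partition
$|E_{1,3}| = 4$, $|E_{2,2}| = 5$, $|E_{2,3}| = 8$, $|E_{3,3}| = 3$. The
package carries both that partition and an explicit edge-list realisation of
the graph:

```{r diclofenac}
round(compute_all(diclofenac_partition()), 3)
```

One printed cell deserves a note: the published Sombor value 68.363 is a
truncation of 68.3636; half-away rounding gives 68.364. Comparisons against
printed values are therefore made at printed precision (agreement within
one unit in the last printed digit), not by string equality.

# Recovering partitions from printed indices

The study prints index values for all 22 drugs but no other graphs, so the
only auditable route from a printed row back to a degree structure is
inversion: find nonnegative integer counts $n_{a,b}$ (10 unknowns for
maximum degree 4) matching the four integer-valued indices $M_1$, $M_2$,
$HM$, $F$ exactly and minimising the squared deviation over the seven
remaining indices. `recover_partition()` does this by compiled
branch-and-bound: depth-first enumeration over degree pairs in decreasing
$a^2+b^2$ order, pruned by suffix windows on the achievable $M_2$ and $F$
consumption per unit of $M_1$. Since $HM = F + 2M_2$ identically, $HM$ is
checked first and the search runs on the three independent budgets.

Two design points:

* **Uniqueness.** The eleven per-edge weight vectors are linearly
  independent over the rationals (a consequence of the rational independence
  of $\sqrt{2}, \sqrt{3}, \sqrt{5}, \sqrt{6}, \sqrt{7}$ appearing in the
  $N$ and $SO$ rows), so an index vector computed exactly from a real graph
  determines its partition uniquely. For rounded printed data the optimum
  could in principle tie; ties are broken by lexicographically smallest
  count vector and uniqueness is reported.
* **Infeasibility is information.** A printed row violating
  $HM = F + 2M_2$ cannot come from any graph; `recover_partition()` raises a
  classed error carrying the identity gap and the best achievable residual.
  Five published rows (Ketorolac, Lifitegrast, Methylprednisolone,
  Rimexolone, Tacrolimus) are in that position, and `reproduce_all()`
  records them as infeasible rather than repairing them.

# Fixture transcription and validation

The published tables were transcribed with two cross-checks applied during
packaging, both of which a user can re-run:

* every index row was checked against the identity $HM = F + 2M_2$
  (`validate_index_table()`), and where a concatenated print rendering
  admitted more than one digit grouping, the identity-consistent grouping
  was chosen;
* the full 7 × 11 correlation table recomputed from the packaged tables
  agrees with the published one to within 0.0005 per cell for ten of the
  eleven index columns, which pins the transcription at printed precision.
  The Randić column is the exception: its published correlation row cannot
  be reproduced from the published tables themselves (deviations up to
  0.10), an internal inconsistency of the source data that the deviations
  report records.

# Regression conventions

* **Missing data.** Five property cells are missing. Fitting uses listwise
  deletion on the response only (the index table is complete), which
  reproduces each published model size: $n = 21$ for BP, P, E, C, MW and
  $n = 22$ for MR, MV.
* **Statistics.** With $k$ regressors and SSE the residual sum of squares:
  $SE = \sqrt{SSE/(n-k-1)}$, $RMSE = \sqrt{SSE/n}$, $R^2 = 1 - SSE/SST$,
  $r = +\sqrt{R^2}$, $F = (R^2/k)/((1-R^2)/(n-k-1))$, and $p$ the upper-tail
  F probability. The $RMSE = \sqrt{SSE/n}$ convention is stated explicitly
  because the source never defines it: it is the only convention consistent
  with every published $(SE, RMSE, n)$ triple for the ten-regressor models,
  e.g. $2.057^2 \cdot 10/21 \approx 1.419^2$. (The published Model 1 pair is
  not consistent with any shared convention and is recorded as a deviation.)
* **No standardisation.** Regressors enter on their raw scales, as the
  published coefficient magnitudes imply. Published $p$ values of
  0.00/0.000/0.001 are treated as upper bounds, not reproduction targets.
* **Prediction.** Predictions use the full-precision refit coefficients and
  are produced for all 22 drugs, including drugs excluded from a fit because
  their response is missing. The refit coefficients differ somewhat from the
  published (3-decimal) ones: with ten highly collinear regressors and
  $n \le 22$, third-decimal rounding of the design matrix visibly shifts
  individual coefficients while barely moving fitted values. This is why
  fitted-value agreement with the published predictions is at the few-0.01
  level rather than exact.

# MCDM configuration

The source states the two methods and their weight philosophies (equal
weights for TOPSIS, ratio weights for VIKOR) but not which matrix feeds
each method, the numeric weights, or the handling of the five missing
property cells. The package therefore makes every choice explicit and
configurable, and treats as *load-bearing* only the configuration-robust
outcomes — the drug maximal on every criterion (Tacrolimus) must score
$C = 1$, $Q = 0$, rank 1, and the drug minimal on essentially every
criterion (Cyclosporine) must rank last — which hold under all supported
configurations.

Defaults, and why:

* **TOPSIS**: property matrix (22 × 7), equal weights, vector
  normalisation. Consistent with the published $D^+ = 0$ for Tacrolimus
  (maximal in every property) and a small but nonzero $D^-$ for
  Cyclosporine.
* **Missing cells**: policy `predicted` substitutes the published predicted
  value when one is printed, else the column mean. The published
  predicted table omits exactly the five missing cells, so in practice the
  column mean is used; every substitution is logged in the result and the
  deviations report. `mean` and `drop-criterion` are available; under
  `drop-criterion` only MR and MV survive, since the other five property
  columns each have a missing cell.
* **Per-property VIKOR**: index matrix (22 × 11, complete — no missing-value
  policy involved), weights proportional to the absolute correlations of the
  target property with the 11 indices, $v = 0.5$. The ratio-weight
  prescription maps a property's correlation row onto exactly the index
  criteria, which is why the index matrix is the coherent default here; the
  property matrix with equal weights is the documented fallback. Both
  preserve the extreme ranks.
* **Ties** in any rank column are broken by score and then alphabetically by
  drug name — deterministic and auditable, rather than shared ranks.
* **Printing**: TOPSIS scores at 7 decimals, VIKOR at 6, matching the
  published tables.

Per-cell reproduction of the published TOPSIS/VIKOR score tables is *not*
claimed: it would require the undocumented weight values and missing-cell
policy. Correctness of the implementations is instead established against
independent brute-force oracles on small random matrices (agreement to
1e-12), scale-invariance of $C_i$, and planted dominant/dominated
alternatives.

# Synthetic data: what it emulates and what it does not

The generators exist so that every stage is testable without external data,
with truth known:

* `random_molecular_graph()` grows a random spanning tree (each new vertex
  attaches to a uniformly chosen existing vertex with spare valence, which
  guarantees connectivity without rejection sampling) and then closes rings
  by accepting non-adjacent pairs with probability `extra_edge_prob`
  (default 0.15, giving drug-like ring counts at 10–30 heavy atoms) subject
  to the degree-4 bound. It emulates connectivity and bounded valence —
  *not* chemistry: no aromaticity, heteroatom statistics, or realistic ring
  -size distributions.
* `synth_qspr_dataset()` draws such graphs (default 10–30 vertices, spanning
  the published drugs' size range), computes their true index table and
  simulates the response as a configured linear combination plus
  $\mathcal{N}(0, \sigma^2)$ noise — exactly the model the regression stage
  assumes. Passing recovery tests therefore validates the estimator, not
  the linearity assumption for real molecules.
* `synth_decision_matrix()` draws uniform positive cells and can plant a
  dominant (1.1 × column maxima) and a dominated (0.9 × column minima)
  alternative, mirroring the Tacrolimus/Cyclosporine structure.

All generators are pure functions of their seed: they run in a local RNG
stream and restore the caller's state.

# Numerical choices and degenerate inputs

* All index arithmetic is double precision; the identity $HM = F + 2M_2$ is
  asserted to 1e-9 relative tolerance after every computation.
* The $ABC$ term at a $(1,1)$ edge is $\sqrt{0} = 0$ and is returned with a
  warning (it cannot occur in a connected graph with more than two
  vertices).
* TOPSIS on a matrix of identical alternatives (so $D^+ + D^- = 0$) is an
  error; VIKOR with all-equal $S_j$ defines the $Q$ term as 0 with a
  warning; a criterion with equal best and worst contributes 0 to $S_j$.
* Rank-deficient regression designs and fits with $n \le k + 1$ are errors
  naming the offending columns.
* The partition search carries safety caps on nodes visited and solutions
  stored; for inputs already known infeasible the caps are tightened, since
  the search then only serves the best-residual report.

# Problem sizes in the test suite

The suite validates the identities on 200 random graphs of up to 30
vertices, round-trips partition recovery on 100 graphs of up to 25 edges,
checks interval coverage of the OLS machinery over 500 noise replicates on
a fixed 30-compound design (coverage 95% ± 3%), and cross-checks the MCDM
chains on dozens of small random matrices. These sizes keep the full suite
in the tens of seconds while leaving each property statistically
meaningful.

# Known limitations

* Only degree-based indices: no distance-, eigenvalue- or matching-based
  descriptors.
* No structure perception: graphs enter as edge lists; SMILES ingestion is
  out of scope.
* The regression stage reproduces the published models; it deliberately
  offers no stepwise selection, regularisation or cross-validation.
* Published tables are reproduced as printed; where a printed row is
  internally impossible (the five identity-violating index rows, the
  irreproducible Randić correlation row, the inconsistent Model 1 RMSE),
  the package surfaces the anomaly rather than resolving it.
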