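---
title: "Phenome-wide prediction with weighted patient vectors: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenome-wide prediction with weighted patient vectors: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model the package implements, the
parameters that matter and their defaults, the design decisions taken where
the design was genuinely open, and what the simulation test bed does and
does not establish. Everything quantitative stated here is computed by the
test suite or by `scripts/acceptance.R`; the vignette itself runs no code.

## The prediction model

### Case/control identification

Diagnoses are ICD-9 codes, which encode billing granularity rather than
clinical phenotypes. They are mapped many-to-one-or-more onto phecodes.
For a target phenotype (a phecode), a patient-visit is a **case** if the
visit's phecodes contain the target, otherwise **excluded** if any of the
visit's phecodes falls inside one of the target's *exclusion ranges*
(inclusive decimal intervals such as [427, 427.99]; phecodes are
hierarchical decimals), otherwise a **control**. Exclusion implements the
PheWAS convention that a patient with a related but distinct condition is
not a clean control. Case status dominates: a patient carrying the target
phecode is a case even though the target typically lies inside its own
exclusion range.

Prediction targets *incidence* at the latest visit. A patient is an
**incident case** for a phenotype if they (1) have at least two visits,
(2) are a case at the latest visit, and (3) were never a case at any
earlier visit. A **valid control** satisfies (1) and (3) and is a control
— not excluded — at the latest visit. All other patients are **unlabeled**:
single-visit patients, prior cases, and patients excluded at the latest
visit. Two readings were open here and are resolved as follows. First, a
patient excluded at the latest visit but never a case earlier is kept as
unlabeled rather than dropped, because their sequences still inform the
embedding. Second, a patient who is a case of the target but also carries
other phecodes inside the target's exclusion range remains a case — case
dominance — which is the standard PheWAS behaviour.

Phenotype prevalence is the incident-case fraction among labeled subjects;
phenotypes below a prevalence floor (default 0.05%, strict) or without any
incident case are excluded from evaluation.

### Concept embeddings

Each admission is a set of namespaced concepts (`phe:`, `rx:`, `lab:`);
presence is binary within an admission. Concepts observed in fewer than 50
distinct admissions (strict, counted once over the whole cohort before any
removal) are dropped — too rare for stable vectors. Each patient becomes
one sentence: admissions concatenated in temporal order (ties between
identical admission times broken by admission identifier, for determinism),
concepts randomly permuted *within* each admission, because
within-admission order carries no clinical information and the permutation
prevents the trainer from learning an artifactual one.

Embeddings are trained by a skip-gram model with negative sampling,
implemented in compiled code in the package. The trainer follows the
classic reference implementation: dynamic (uniformly shrunk) context
windows, a 0.75-power unigram table for negative draws, linear learning
rate decay, and frequent-word subsampling. It is single-threaded and
driven by its own xorshift64* generator, so one seed yields byte-identical
vectors — reproducibility is a hard contract here, tested as such.

Parameters, defaults, and reasons:

| parameter | default | why |
|---|---|---|
| `d` (dimensions) | 100 | standard scale for vocabularies of a few thousand concepts |
| `window` | 500 | larger than any realistic admission, so all concepts of a patient document are mutual context |
| `epochs` | 10 | small corpora need more passes than the classic 5 |
| `negative` | 5 | reference default |
| `minCount` | 1 | rare-concept removal already happened upstream |
| `sample` | 1e-3 | reference subsampling threshold; medical vocabularies have no Zipf tail, so most concepts are "frequent" |
| `alpha` / `minAlpha` | 0.025 / 1e-4 | reference schedule |
| `center` | TRUE | see below |

**Mean-centering.** Skip-gram vectors trained on small, dense corpora —
every concept co-occurring with every other — develop a large common
component; raw pairwise cosines then crowd toward 1 and carry almost no
contrast. `trainEmbeddings()` therefore subtracts the vocabulary mean
vector after training (the first step of standard embedding
post-processing). The method's formulas are untouched; unrelated concepts
simply return to cosine ≈ 0, which is what the weighting scheme needs to
discriminate.

Skip-gram versus CBOW was an open choice (the field uses both); skip-gram
is implemented because it behaves better on small corpora with rare
tokens. Embeddings are trained per train/test repeat on training patients
only — every patient not in that repeat's test set, unlabeled patients
included, which is the method's central data-efficiency argument. Labeled
training patients' latest admissions stay in the corpus (embedding is
unsupervised; the incident definitions already prevent label leakage for
labeled subjects).

### Weighted patient vectors and risk scores

For phenotype $j$ with vector $\vec{Phe_j}$ and concept $k$ with vector
$\vec{V_k}$, let $r_{jk} = \cos(\vec{Phe_j}, \vec{V_k})$. A patient's past
records (all admissions before the latest) yield a *multiset* of concept
occurrences — one occurrence per admission in which the concept appears, so
a chronic medication present at five admissions contributes five times.
The tailored patient vector is

$$\vec{PV_{ij}} = \frac{\sum_{k=1}^{K_i} r_{jk}^2 \vec{V_k}}
                       {\sum_{k=1}^{K_i} r_{jk}^2},$$

a convex combination of the patient's concept vectors. The square makes
negative and positive correlations equally informative and the weights
nonnegative. The risk score is $S_{tj} = \cos(\vec{PV_{tj}}, \vec{Phe_j})
\in [-1, 1]$. The unweighted P2V baseline replaces the weighted average by
the plain sum; because cosine is scale-invariant, the two coincide exactly
whenever all $|r_{jk}|$ are equal — a property the tests assert.

The multiset-versus-set reading of $K_i$ was open; the multiset is the
default (consistent with binary-per-admission construction), with
`uniqueConcepts = TRUE` available for sensitivity analysis. A
positive-correlations-only variant (`positiveOnly = TRUE`) is exposed but
not recommended: discarding negative associations discards information.

### Numerical conventions and degenerate inputs

* Cosine with a zero-norm operand is defined as 0, the uninformative
  midpoint.
* A patient vector whose norm is below $10^{-10}$ times the largest
  constituent concept-vector norm is treated as zero and flagged: exactly
  cancelling combinations otherwise leave only floating-point residue
  whose direction is meaningless but whose cosine is not small.
* Patients with no usable (in-vocabulary) past concepts score 0 and are
  flagged rather than dropped — in a screening setting every patient must
  receive a score.
* Out-of-vocabulary concepts are skipped, never zero-imputed; lookup of a
  missing concept is an error, not a silent zero.
* Correlation-matrix entries are clamped to $[-1, 1]$ against rounding.

## Baselines and metrics

The three conventional baselines consume a count matrix: entry (patient,
concept) is the number of pre-latest admissions containing the concept.
Fixed hyperparameters: L1-penalised logistic regression at inverse
regularisation strength $C = 1$ in the per-sample-loss convention
($\lambda = 1/(Cn)$ in glmnet's parameterisation, features not
standardised, convergence threshold $10^{-5}$); random forest with 500
trees and Gini impurity (single-threaded for determinism); gradient
boosted trees with 100 rounds. Everything else stays at the backing
implementations' defaults. One baseline model is fitted per phenotype per
repeat; the embedding methods share one embedding per repeat.

Metrics are implemented from their definitions and cross-checked in the
tests against exhaustive oracles (and pROC for AUC-ROC): rank-based
AUC-ROC with ties counted ½; AUC-PR as average precision (step-wise
integral, no interpolation); max-F1 as the maximum over thresholds placed
at every distinct score, which for finite samples is exactly "all possible
thresholds". The all-positive operating point is always available, so
max-F1 is never below $2p/(1+p)$ at case fraction $p$. Phenome summaries
report medians and quartiles per bin of 300 phenotypes ranked by
descending prevalence, and head-to-head win counts use strict inequality
on repeat-averaged metrics — a tie is not a win.

## The simulation test bed

### What it emulates

A population pool of 20 000 patients, each carrying 150 correlated binary
concepts; the first 10 are signal concepts driving a binary outcome
concept `sim:C0` through a logistic model with shared coefficient $\beta$
(grid 0.2–0.8), intercept solved by bisection so pool outcome prevalence
is 0.5; case-control replicates of 10 cases and 190 controls (1:19, i.e.
5% prevalence; 1:1, 3:7 and 1:9 are supported) drawn for training and
test, disjoint within a replicate.

The exact correlation structure of the concepts was not available to this
implementation, so the generator is an explicit stand-in, isolated behind
its interface and fully parameterised: a latent *block*-exchangeable
Gaussian threshold model. Concepts form blocks of `blockSize = 10` sharing
a latent factor ($Z = \sqrt{\rho}\,W_{block} + \sqrt{1-\rho}\,E$,
thresholded at the marginal probability), emulating how medical concepts
correlate in clusters — comorbid conditions and their care patterns —
rather than globally. Defaults: marginal presence 0.2 (about 30 concepts
per record) and within-block latent correlation 0.5 (pairwise binary
correlation ≈ 0.33). These were fixed once, on structural grounds: with a
*global* shared factor, every noise concept aligns with the corpus's
dominant embedding direction and profile-based cosine similarity inverts
the association ordering (a PPMI-SVD analysis of the corpus shows the
same inversion, so it is a property of that corpus geometry, not of the
trainer), which contradicts the qualitative behaviour this test bed
exists to exhibit: embedding cosines that recover association strength.
Under the block model the recovery property holds and is asserted by the
acceptance tests.

Each simulated patient has a single admission (the scenario carries no
temporal structure). In the embedding corpus, cases carry the outcome
token `sim:C0` — exactly as real unlabeled patients' records carry their
diagnoses — which is how the outcome concept acquires a vector; in every
feature view (scoring and count matrices) the token is withheld.

### Experiment design

Per $\beta$: the pool's first 10 000 patients are an unlabeled embedding
background; case-control draws come only from the other half, so no test
subject ever contributes a sentence. Each replicate trains its own
embedding ($d = 32$, window 500, 5 epochs, 5 negatives — sized for the
151-token vocabulary) on a fresh 1000-sentence background subsample, so
the replicate distribution integrates over embedding noise, then scores
the test set with the weighted and unweighted methods and fits the three
count baselines on the training draw. Training embeddings on the
200-subject labeled draw alone was evaluated and rejected: such corpora
are too small to give the outcome concept a stable vector, and the
resulting geometry cannot separate any methods — the background design is
also the faithful one, since the method's premise is that unlabeled
patients inform the embedding.

Problem sizes used by the shipped checks (the package's own choices,
documented here so results are interpretable): null calibration at
$\beta = 0$ uses 200 replicates; the signal-strength grid
$\beta \in \{0.2, 0.5, 0.8\}$ uses 100 replicates per $\beta$ in the
acceptance suite and script; embedding-recovery probes use 12 replicates
per $\beta$; unit-level smoke runs use pools of 3000–4000. Monte-Carlo
error of a median over $n$ replicates is about $1.25\,\sigma/\sqrt{n}$,
and the monotonicity checks allow adjacent-grid inversions within that
error.

### What passing does and does not show

The simulator establishes *mechanism*, not clinical performance: that the
pipeline's embeddings recover planted associations, that every method is
calibrated to AUC 0.5 under the null, that discrimination rises with
signal strength, and that tailored weighting dominates the unweighted sum
at moderate-to-strong signal. Real records differ in ways the generator
deliberately omits: temporal structure across admissions, Zipf-tailed
vocabularies of thousands of concepts, informative visit counts,
missingness correlated with care intensity, and phenotype label noise.
Results on the simulator therefore do not certify real-data AUCs; the
cohort pipeline is instead tested separately on hand-enumerable fixtures.

## Reproducibility

All randomness flows from one master seed through named sub-streams
(`substreamSeed`): splitting, shuffling, embedding initialisation and
negative draws, pool generation, replicate draws. Repeats are independent
yet reproducible, adding a stream never perturbs existing ones, and every
CLI run writes its resolved configuration beside its outputs. The
embedding trainer is single-threaded by construction; ranger and xgboost
run single-threaded so their fits are bit-reproducible.

## Known limitations

* ICD-9 only; no ICD-10 mapping, no phecode rollup hierarchy beyond
  exclusion ranges.
* Binary per-admission presence; continuous lab values are not used.
* No temporal decay: an admission ten years ago weighs as much as last
  month's.
* Scores are cosines, not calibrated probabilities.
* The full PheWAS phecode map is not shipped (size and licensing); the
  loader accepts any CSV in the documented dialect.
* Embedding transferability across databases is untested here.
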