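---
title: "Modelling the cost-effectiveness of colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crcscreen` implements a Markov cohort (state-transition) model of the
colorectal adenoma–carcinoma sequence with a screening and surveillance
overlay, an economics layer and an uncertainty layer. This vignette is the
package's own account of the model: the structure and its assumptions, the
parameters that matter, the design choices made where the source material is
silent, and what the synthetic-data tests do and do not demonstrate.

## The natural-history model

A closed cohort enters at age 30 with no colorectal neoplasia and is
simulated in annual cycles to age 100. Health states are defined by the
index lesion: normal epithelium; low-risk (<10 mm) and higher-risk
(≥10 mm) adenomas; pre-clinical (undiagnosed) cancer by AJCC stage I–IV;
clinical (diagnosed) cancer by stage; post-polypectomy surveillance; and
three absorbing death states (colorectal cancer, endoscopic perforation,
other causes). Adenomas and pre-clinical cancers carry a distal/proximal
location, split 70:30 at onset, so that the limited reach of flexible
sigmoidoscopy can be represented. Fourteen percent of cancers arise
directly from normal epithelium (inflammatory bowel disease, flat or
serrated lesions) as stage I disease without passing through an adenoma.

Annual transition probabilities (`nh_params()`):

* `p_onset` — normal → low-risk adenoma, varying by 10-year age band
  (30–39 … 70+). Age banding is a design choice: the onset of neoplasia is
  strongly age-dependent, while downstream progression rates are taken as
  age-constant to keep the calibration identifiable.
* `p_low_high`, `p_high_crc` — adenoma risk-class progression and malignant
  transformation (progression only; no regression).
* `p_prog` (I→II, II→III, III→IV) and `p_sympt` (stage-specific symptomatic
  presentation) govern the pre-clinical sojourn. How undiagnosed cancers
  surface without screening is not observable directly; stage-specific
  annual presentation probabilities are the package's modelling choice and
  are calibrated.
* `p_crc_death` — stage-specific annual probability of cancer death while
  in a clinical state, applied indefinitely (no cure point), constrained
  non-decreasing in stage. Survival structure is therefore implicit and
  absorbed into the calibration against mortality targets.

Other-cause mortality comes from a life table as an age-dependent annual
probability. Competing risks are composed multiplicatively: disease
transitions (including cancer death from clinical states) first, then every
live destination is scaled by `1 − q_other(age)`. At age 100 the life table
forces absorption. No half-cycle correction is applied by default —
outcomes are counted at cycle end on annual cycles; `half_cycle = TRUE` in
the accumulation switches to start/end averaging for QALY occupancy.

The direct (non-adenoma) pathway is enforced as a flow-ratio constraint at
parameterisation time: `resolve_direct_pathway()` fixes a scale so that
direct onsets are 14% of all cancer onsets over a full no-screening run,
rather than renormalising per cycle. The direct rate follows the age shape
of adenoma onset (with a flat fallback if the adenoma pathway is disabled),
since the age profile of de-novo cancers is not separately observable.

## Screening and surveillance overlay

Three core strategies and five age variants are built in: biennial gFOBT
with reflex FIT at 55–74 (and 55–64, 65–74), biennial FIT for the same age
groups, and once-only flexible sigmoidoscopy at 60 (or 55). The overlay
redistributes the cohort at screening time points by expected value — a
deterministic cohort calculation, no Monte Carlo at the cohort level.

Attendance is modelled by partitioning the population once into
never-attenders (13%, faecal strategies only — they still receive and cost
invitations) and potential attenders who participate in each round
independently with probability 0.53/0.87 ≈ 0.61, reproducing the 53%
overall per-round uptake. The published material gives both the uptake and
the never-attender fraction but not their joint model; independent
per-round attendance within the potential-attender pool is the package's
choice.

A positive faecal cascade is: primary test positive → (reflex FIT positive,
applied independently with full processing cost and no second dispatch
cost) → colonoscopy referral at 86% compliance, with 5% of referrals routed
to CT colonography (the published fraction is not stated; 0.05 is a
configurable default). Non-compliers return to the routine pool rather than
being lost forever. At colonoscopy, detection follows the colonoscopy
operating characteristics; detected low-risk adenomas are removed and the
member returns to routine screening, detected higher-risk adenomas are
removed and enter surveillance (29% on the annual high-risk schedule, 71%
on the 3-yearly intermediate schedule), detected cancers enter
stage-specific clinical states tagged screen-detected. Disease-free
referrals undergo a clear colonoscopy that is costed and carries
complication risk but no pathology cost. CT colonography positives are
confirmed by colonoscopy. Sigmoidoscopy removes detected distal low-risk
adenomas at the visit (within the FSIG fee, plus pathology), refers
higher-risk and cancer findings to colonoscopy, and treats proximal
lesions via `1 − specificity` like disease-free attenders.

Surveillance time-keeping uses tunnel states — risk schedule × years since
last exam × clear-exam count — each retaining the full lesion sub-state so
that new neoplasia can develop and be found under surveillance. A clear
exam moves a high-risk member onto the 3-yearly schedule with one clear
banked; two clear exams 3 years apart exit to the routine pool; any adenoma
finding resets the clock. Surveillance compliance (86%) is applied per
exam.

Within a cycle the event order is: screening round (if scheduled),
surveillance exams, natural-history progression, competing deaths,
surveillance-clock advance. The ordering is a documented convention; the
source material does not state one.

Perforation (with polypectomy 0.216%, without 0.107%, sigmoidoscopy
0.002%), perforation death (5.195% / 6.452%) and major bleeding are applied
per procedure; fatal perforations remove cohort mass into a dedicated
absorbing state.

## Economics

Costs are 2008 euro from a third-party-payer perspective: kit dispatch per
invitee, kit processing per participant, procedure fees, complication
management, polypectomy pathology (per-adenoma cost × 1.9 adenomas removed
per person), and lifetime stage-specific cancer-management costs charged as
a lump sum at the diagnosis cycle — they are lifetime aggregates by
construction, so spreading them over survival would double-discount.
Surveillance- and screen-detected cancers use the screen-detected cost
schedule; symptomatically presenting cancers the symptomatic schedule.
Utilities are 0.94 cancer-free (including pre-clinical cancer, which is by
definition unfelt) and 0.80 in every clinical stage, accrued per year lived.

Both streams are discounted at 4%/year with reference age 55. Ages below 55
carry a factor of 1; because no strategy differs from no screening before
55, every incremental comparison is invariant to this convention.
`efficiency_frontier()` removes strictly dominated strategies, then
iteratively removes extended-dominated ones until the frontier ICERs
strictly increase — the lower convex hull of the cost-effectiveness plane,
which the test suite checks against a brute-force oracle.

## Calibration

Unobservable natural-history parameters (18 coordinates) are estimated by
random-walk Metropolis–Hastings against a normal likelihood over
age-banded cancer incidence by stage, cancer mortality, and adenoma /
undiagnosed-cancer prevalence, each observation with its own standard
deviation. Priors are flat Beta(1,1) on [0,1], entering only as a support
constraint; parameter sets violating the model's support (including
non-monotone stage-specific fatality or pre-clinical exit probabilities
above 1) score `-Inf`.

The proposal is a symmetric Gaussian random walk on the probability scale
with out-of-support rejection, not a logit-scale walk: a logit walk
targeting a flat-on-probability prior needs a `p(1−p)` Jacobian in the
acceptance ratio, which conflicts with the simple
`min(1, exp(Δ log L))` acceptance rule the sampler is specified and tested
against; rejection at the boundary achieves the same support restriction
with exact semantics. Proposal scales are tuned toward 20–40% acceptance
during burn-in (frozen afterwards). Three chains are run by default; the
pooled post-burn-in samples provide (a) the highest-likelihood sampled set
used for base-case analyses (no separate optimiser, matching the "MAP from
sampled set" convention) and (b) joint natural-history draws for the PSA,
preserving the correlation among transition probabilities.

## Uncertainty analysis

One-way sensitivity analyses re-simulate the model at each endpoint of a
parameter's stated range. The tornado table orders parameters by the width
of the resulting ICER range. The PSA draws every distribution-bearing
parameter per iteration; parameters flagged as inter-dependent (the
adenoma/cancer sensitivities of one test) share a single uniform quantile,
giving perfect rank correlation. Natural-history sets are resampled from
the calibration posterior per iteration. The CEAC evaluates, on a
willingness-to-pay grid of €0–50,000 in €500 steps, the probability that
each strategy has the highest net monetary benefit; 95% confidence
ellipses are bivariate-normal contours from the sample mean and covariance
of the incremental (QALY, cost) cloud.

One printed distribution is internally inconsistent: the FIT cancer
sensitivity is given as Beta(35.29, 143.08), whose mean (0.198) cannot be
reconciled with its 71% base case and 67–75% range, while
Beta(350.29, 143.08) reproduces both exactly — almost surely a dropped
digit. The package defaults to the re-parameterised shape and keeps a
`fit_beta_verbatim` switch for the value as printed.

## Synthetic data: what it emulates, and what it does not

No registry or national life-table data ships with the package. The
synthetic-data module generates (a) a Gompertz life table,
`q(a) = 1 − exp(−α e^{βa})` with α = 2.2×10⁻⁵, β = 0.097 — the scale of a
modern western-European national life table — and (b) calibration targets
produced by running the natural-history model forward under a known "true"
parameter set and adding normal observation noise (5% CV by default), in
5-year age bands 50–84 for incidence and mortality and at ages 55/60/65
for prevalence.

The default true parameter set was fixed once by fitting the no-screening
model to the scale of the published aggregate outcomes — lifetime cancer
incidence ≈ 5,100–5,400 and mortality ≈ 2,300 per 100,000 cohort members
with a 12/25/33/30 stage split — together with a priori prevalence targets
(adenoma prevalence 10/12/15% and undiagnosed-cancer prevalence
0.4/0.6/0.8% at 55/60/65, in the range of modern autopsy and
screening-pilot estimates) and field-typical dwell times. It is a
synthetic stand-in, documented as such, not the published calibrated
transition set, which was never deposited. Consequences follow for what
the tests show: parameter-recovery and property tests validate the
machinery (mass conservation, calibration coverage, frontier logic,
discounting identities) on data whose generating process is the model
itself — they cannot validate the biological adequacy of the dwell-time
structure, and incremental economics are sensitive to exactly that.
Detection-route balances and procedure volumes land close to the published
ones under this stand-in, while the screening-induced incidence reduction
runs larger, which propagates into more favourable (cost-saving) ICERs than
the published base case. The acceptance material reports these honestly.

## Numerical choices and problem sizes

* Cohort engine: dense matrix products over the 22-state public space (the
  overlay works on an expanded blocks × lesions representation with
  surveillance tunnels); mass conservation holds to 10⁻¹² over the full
  70-cycle run and the fast engine is pinned to the reference
  transition-matrix path to the same tolerance.
* Direct-pathway resolution: fixed-point odds matching to an absolute
  tolerance of 10⁻⁴ on the achieved fraction, warm-started inside MCMC.
* Default analysis sizes, chosen as the package's standard desk-scale
  settings: calibration with 3 chains × (500 burn-in + 1,200 retained);
  parameter-recovery experiments with 20 replicate target sets × 5,000
  pooled post-burn-in samples; PSA at 300 iterations in the analysis
  scripts (the reference analysis used 1,200; both are single parameters).
* Ties in the frontier are broken by cost at equal effectiveness;
  undefined ICERs (zero QALY difference) are flagged, not computed.

## Known limitations

* Cohort (not individual-level) simulation: no between-individual
  heterogeneity in risk or attendance beyond the never-attender split.
* Intermediate- and high-risk adenomas are lumped (≥10 mm) with a fixed
  29% high-risk share among surveillance entrants.
* No adenoma regression; low-risk adenomas cannot present directly as
  cancer except through the lumped direct pathway.
* Quality-of-life decrements of screening episodes, programme set-up and
  societal costs are out of scope, as in the reference evaluation.
* The stage-specific cancer-death probabilities have no cure point; very
  long-horizon survivorship is therefore pessimistic, absorbed by
  calibration but not structurally validated.
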