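---
title: "Model and methods: virtual pembrolizumab trials in metastatic TNBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tnbcqsp` is a quantitative-systems-pharmacology platform for metastatic
triple-negative breast cancer (TNBC): a mechanistic ODE model of
tumour--immune--drug dynamics across nine compartments, a virtual-trial
engine for pembrolizumab monotherapy scored by RECIST v1.1, and a
biomarker-discovery layer. This vignette is the package's own account of
the model, its assumptions, and the design choices that were genuinely
open.

## Compartment structure and state

The model has nine compartments: central (blood), peripheral tissue, four
tumour compartments -- the primary breast tumour, two lung metastases
(lungs are the most frequent TNBC metastatic site, and RECIST counts at
most two target lesions per organ) and one "other" metastasis -- and three
tumour-draining lymph-node compartments (primary, lung, other; both lung
lesions drain into the lung node). The state vector has 239 entries
(`qsp_state_names()`).

Each tumour compartment carries: five cancer clones, dead cells, a dynamic
carrying capacity $K$, eight neo-epitope-specific active cytotoxic T-cell
pools plus one exhausted pool, helper T cells, regulatory T cells, M1/M2
macrophages, MDSCs, immature and mature antigen-presenting cells, nine
antigen pools (eight neo-epitopes + self), the cytokines IL-10, IL-12,
IFN-$\gamma$, TGF-$\beta$ and CCL2, angiogenic factor, arginase-I, nitric
oxide, PD-L1 surface density and local antibody concentration. Lymph nodes
carry naive CD4/CD8 pools, mature APCs, per-specificity activated T cells,
Th/Treg activation pools, IL-2 and antibody. Units: cells, nM for soluble
species (antigen pools included), molecules/cell for surface species, days.

## Governing mechanisms

One governing equation per species, built from four mechanism classes:

**Gompertzian clonal growth.** Clone $c$ grows as
$k_{g,c}\,N_c \ln(K/N_{tot})$, with the log term clipped below at $-10$
when the burden exceeds the capacity (stiffness bound). The capacity obeys
$\dot K = k_{Kg} K \frac{A}{A+EC_{50}}(1 - K/K_{max}) - k_{Kd}(K-K_{min})$,
where $A$ is the angiogenic factor secreted by cancer cells and M2
macrophages. $K_{min}$ ($10^7$ cells) is the baseline vascular support
that lets a freshly seeded micro-metastasis grow before angiogenesis
engages; $K_{max}$ ($10^{11}$ cells, a $\sim$5.8 cm sphere) is a vascular
ceiling. Both bounds enter as smooth factors rather than hard clips: hard
clipping makes the right-hand side discontinuous and the stiff solver
chatters on the boundary. The ceiling only matters far past any RECIST
progression call; without it non-responding lesions grow exponentially
without bound and eventually break the integration.

**Hill-type modulation.** Every cytokine or receptor effect is a
saturating Hill term: antigen-driven APC maturation (IL-12 promotes,
IL-10 inhibits), TCR ligation by presented peptide--MHC (coefficient 2),
PD-1 pathway inhibition (Hill in the ligand-bound PD-1 fraction,
coefficient 2, EC$_{50}$ 0.5), CCL2-driven myeloid recruitment,
cytokine-modulated M1/M2 polarization, and suppression of cytotoxicity by
TGF-$\beta$, arginase-I and NO as products of inhibitory factors
$EC_{50}/(EC_{50}+s)$.

**First-order kinetics.** Cancer apoptosis releases antigen into the
tumour pools; dead cells clear; cytokines degrade; T cells die, egress,
traffic and exhaust at first-order rates; PD-L1 relaxes toward a baseline
plus an IFN-$\gamma$-induced component (relaxation rate 0.2/day).

**Competitive binding at quasi-equilibrium.** PD-1 binding to PD-L1,
PD-L2 and the blocking antibody is solved algebraically at every
right-hand-side evaluation from the conservation equations (receptor and
ligands depleted; the antibody taken in molar excess, being replenished
from the 5 L central pool). The scalar free-receptor equation is solved by
bisection; the identical solve is exported as `checkpoint_occupancy()` and
is validated in the tests against an independent `uniroot` oracle to
$10^{-8}$ relative error. The immune synapse treats CD28 and CTLA-4
competing for a pooled CD80/CD86 ligand the same way (CTLA-4 level fixed;
CTLA-4-directed therapy is out of scope). Treating binding as
quasi-equilibrium instead of explicit on/off ODEs removes the fastest
timescales from the system.

**Antigen presentation** collapses cleavage, MHC loading and transport to
a quasi-steady presentation level per epitope,
$p_e = P_{max}\, Ag_e/(Ag_e + \alpha K_{d,e})$, retaining the
peptide--MHC dissociation-constant dependence needed for sensitivity
analyses. Clones differ in which neo-epitopes they express (a fixed binary
matrix by default), and cytotoxic T cells of any specificity kill every
clone; the total kill flux
$k_{kill} C \frac{R}{R + R_{1/2}} (1 - H_{PD1}) \prod_s \frac{EC_s}{EC_s + s}$
(with $R$ the T:C ratio) is apportioned across clones proportional to
abundance. The number of divisions of freshly activated T cells is a
linear sum of TCR, CD28 and IL-2 contributions; output is amplified by
$2^{n_{div}}$.

**Trafficking.** Naive T cells recirculate between central, peripheral and
lymph-node compartments (the initial state places them at the closed-form
steady state of that linear subsystem); activated cells egress to blood
and infiltrate tumours at a rate proportional to lesion volume times a
vascular volume fraction.

**Pharmacokinetics** are linear and mammillary: clearance from central
(0.05/day from a 5 L central volume, i.e. a clearance of 0.25 L/day
and an effective post-distribution half-life near 25 days, typical of
pembrolizumab),
central--peripheral and central--tumour exchange, unidirectional
tumour-to-draining-node lymph flow and node-to-central return. A 200 mg
bolus into 5 L at 149 kDa raises the central concentration by 268.5 nM.
Doses are instantaneous (negligible simplification at 3-week spacing);
there is no target-mediated disposition. The drug states form an
autonomous linear subsystem, which the tests exploit: its matrix
exponential is an exact oracle, and volume-weighted mass balance closes to
$10^{-6}$.

## Numerical choices

`deSolve::lsoda` on a compiled right-hand side; rtol $10^{-6}$, atol
$10^{-3}$ cells / $10^{-9}$ nM, maximum step 1 day, output on a fixed
1-day grid. Doses and metastatic seedings are solver events. Small
negative excursions (beyond $10\times$ atol) are clipped to zero with a
warning after integration; rate laws internally evaluate
$\max(x, 0)$ so transient undershoots cannot feed back. Non-finite states
or derivatives raise an error naming the offending species. Lesion
diameter treats a lesion as a sphere of cancer-cell volume only
($10^{-9}$ mL/cell): $d = (6 N v / \pi)^{1/3}$; immune and stromal volume
are ignored, a systematic simplification.

## Virtual patients and what the generator emulates

A virtual patient is one draw of ~37 Latin-hypercube dimensions:
clone growth rates (log-normal, sdlog 0.25 around 0.035--0.055/day),
killing rate, PD-L1 baseline, exhaustion rate, infiltration rate,
activation rate, clonotype number, Th$\to$Treg trans-differentiation,
eight peptide--MHC dissociation constants, per-tumour (independently
drawn) myeloid recruitment rates and APC baseline, per-lesion log-normal
seeding times (lung median 150 d, other median 100 d, sdlog 0.8 before
calibration), and a per-patient target diameter (log-normal, median
1.65 cm, sdlog 0.25). Each seeded lesion starts from 100 cells split by a
symmetric Dirichlet clone composition. The primary tumour is empty
(resected) unless `primary_tumor_intact`.

Burn-in integrates the untreated model from the earliest seeding until any
lesion reaches the patient's target diameter (accepted; that state is the
treatment baseline) or a 1500-day horizon (rejected). Solver failures are
logged separately from filter rejections. Two handles are calibrated at
cohort level by `calibrate_trial_handles()`: the lung seeding-time median
against a 65% lung-metastasis prevalence (bisection on the log scale;
prevalence is monotone decreasing in the median because later-seeded lungs
are absent when another lesion triggers baseline first), and the
target-diameter median against a 1.65 cm cohort median (near pass-through,
proportional secant). Calibration, tests and the acceptance script use
200-patient cohorts -- large enough that the binomial noise on prevalence
($\approx$3.4 pp) sits inside the ±5 pp tolerance, small enough to run on
one CPU in minutes.

What passing these checks does **not** show about real data: the
generator's distributions are representative choices, not fits to a
clinical population; the model's response rates are emergent and were not
calibrated to published trial tables; and the synthetic fixture used by
the biomarker-recovery tests assigns responder labels by a noisy threshold
rule on one candidate (`make_fixture_cohort()`, documented as synthetic),
so it validates the ranking machinery, not the biology of any particular
biomarker.

## Trial scoring

Treatment is 200 mg every 3 weeks. Assessments every 9 weeks; RECIST
v1.1 thresholds from the standard: CR when every lesion is below a 2 mm
disappearance threshold, PR at $\le$70% of the baseline sum, PD at
$\ge$120% of the nadir with a $\ge$5 mm absolute increase; vanished
lesions contribute 0 to the sum. Stable disease requires a non-PD
assessment at or beyond 24 weeks from treatment start; otherwise the
patient is PD by default. No confirmation scan is required. Time to
response is the first CR/PR assessment; duration of response runs to the
first subsequent progression or to the end of simulation. Responders for
biomarker purposes are CR/PR/SD. Trial endpoints get percentile-bootstrap
95% intervals (1000 resamples, seeded).

## Biomarker machinery

Candidates are baseline quantities averaged over each patient's metastatic
lesions (and their draining nodes): densities, ratios (M2:M1, Treg:Tcyt,
suppressive:activating with suppressive = Treg+M2+MDSC and activating =
Tcyt+Th+M1), TIL and immune fractions, exhausted-T fraction, PD-L1,
cytokines, cancer-clone richness/Shannon/evenness, lymph-node T-cell
diversity over the eight specificities (scaled by clonotypes per
specificity for clone counts), APC density (mature + immature pooled, a
deliberate choice), lesion geometry. Richness uses a 1-cell extinction
threshold because continuous ODE states never reach exact zero; evenness
$J = H/\ln S$ is undefined for $S \le 1$ (reported as 0 in candidate
columns to keep them rankable).

Subgroups take 8 uniformly spaced *interior* cutoffs across a candidate's
observed range (endpoint cutoffs always produce one empty, one full
subgroup and carry no information), each in both directions (value
$\ge$ cutoff / value $<$ cutoff), discarding subgroups under 20 patients.
Scores are the response probability (responder fraction in the subgroup)
and the responder inclusion score, RIS = (captured responders / all
responders) − (captured nonresponders / all nonresponders). Candidates are
ranked by their best subgroup; ties break toward the larger subgroup, then
by name, so rankings are reproducible. Pairs intersect one condition per
candidate ($\le$256 combinations before the size filter) and report the
signed percent change against the better constituent -- a conjunction is
*not* guaranteed to beat its parts. Bootstrap intervals resample patients
with the threshold rule frozen (the least-assumption reading of
bootstrapped subgroup error bars). The sensitivity layer reuses the same
machinery with varied-parameter values as candidates and 15 cutoffs, and
`perturb_fixed_parameter()` re-simulates the identical cohort under
0.5--1.5$\times$ scalings of a fixed parameter, reporting the response
rate and the PD/SD/PR-CR transition matrix against the unperturbed run.

## Abundance calibration

`reference_abundance_states()` simulates one reference patient with an
intact primary, one lung and one "other" lesion seeded together and
captures each lesion's state at the first day it reaches 1 cm -- a
matched-burden rather than matched-time comparison, since lesions of equal
size are what deconvolution-derived ratios compare. Cell fractions divide
each type by all cells in the lesion, cancer included; the
metastasis:primary fraction ratios feed a mean squared log-ratio loss
(ratios are multiplicative). `fit_metastasis_params()` minimizes that loss
over per-site multipliers on myeloid recruitment, M1$\to$M2 polarization
and APC baseline (Nelder--Mead on log-multipliers, box [0.1, 10], 200
evaluations). The shipped target table is a synthetic stand-in encoding
qualitative directions (reduced lymphocyte fractions in metastases, MDSCs
proxied by monocytes) with wide tolerances; substitute your own
deconvolution output for real work. Parameter recovery on self-generated
targets is exact to well within 10%.

## Known limitations

Tumours are well mixed (no spatial structure); non-target and new lesions
are not modelled, so progression can only arise from target-lesion growth;
there is no chemotherapy arm, no immunogenicity, and no overall-survival
layer; the reduced-order system carries one equation per species rather
than the full mechanistic depth of large published QSP models, so absolute
response rates should be read as emergent model behaviour, not
predictions; and exhausted T cells are assumed to have no residual killing
activity.
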