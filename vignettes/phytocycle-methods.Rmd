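---
title: "Model and methods: the plant cell-cycle network and cell-size homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the plant cell-cycle network and cell-size homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phytocycle` simulates a parsimonious ordinary-differential-equation model of
the protein network that drives the plant cell cycle, embeds it in growing,
stochastically dividing cells, and asks under which assumptions the resulting
cell population maintains a stable size distribution.  This vignette is the
package's own account of the model, its parameters, the numerical choices,
and the places where the design was genuinely open.

## 1 The network model

Twelve protein species are tracked, each as a **total mass** (not a
concentration — volume is itself a dynamic variable, and concentration is
mass/volume):

* G1/S module: the kinase–cyclin complex CDKA:CYCD; its stoichiometric
  inhibitor KRP; the transcription factors E2FA and E2FB; the E2F-sequestering
  repressor RBR (the plant ortholog of yeast Whi5); and the F-box protein
  FBL17, which targets KRP for degradation.
* G2/M module: the mitotic kinase–cyclin pool CDKA/B:CYCB; its stoichiometric
  inhibitor SMR; the repressor MYB3R3 and the autoactivating activator MYB3R4
  of the mitotic transcriptional program.
* Linking ubiquitin ligases: SCF and APC, which reset the two cyclin pools.

Cell volume grows exponentially, \(\dot V = r_{gr} V\).  Protein synthesis is
**size-dependent** by default — the synthesis rate scales with \(V\), so the
concentration of such a protein is size-invariant at steady state.  Four
inhibitors (KRP, RBR, MYB3R3, SMR) can instead be switched to
**size-independent** synthesis (constant rate, so growth dilutes them); this
is the indicator \(\mathbf 1_X(V)\) in the synthesis terms, equal to \(V\) or
\(1\).

Fast reactions are resolved by a quasi-steady-state (QSSA) layer evaluated at
every right-hand-side call:

* **Reversible binding** of totals \(A_T, B_T\) with dissociation constant
  \(k_D\): the complex is the smaller root of
  \(C^2-(A_T+B_T+k_DV)C+A_TB_T=0\) (`qss_complex()`, evaluated in the
  cancellation-free form \(2A_TB_T/(s+\sqrt{s^2-4A_TB_T})\)).  Binding pairs:
  CDKA:CYCD–KRP, E2FA–unphosphorylated RBR, CDKA/B:CYCB–SMR.
* **Phosphorylation** of a substrate by kinase mass \(A\): the
  phosphorylated share is \(A/(A+k_{dp}V)\) (`phospho_fraction()`), i.e.
  saturating in the kinase concentration.  Free CDKA:CYCD phosphorylates RBR
  (inactivating it); free CDKA/B:CYCB phosphorylates MYB3R3 (inactivating),
  MYB3R4 (activating) and SMR (marking it for faster decay).
* **Transcriptional regulation**: synthesis
  \((r_B + r_{BA}\,A/(k_{at}A+V))\cdot\mathbf 1_B(V)\)
  (`regulated_synthesis()`).  Free E2FA induces E2FB and FBL17; E2FB drives
  CDKA/B:CYCB and SCF; phosphorylated MYB3R4 drives itself, APC and
  (optionally) KRP.
* **Mediated degradation** at rate \(d\,[\mathrm{mediator}]\) acting on the
  total mass of the target: FBL17 degrades KRP, APC degrades both cyclin
  pools (and SCF can degrade CDKA:CYCD, though its default rate constant is
  zero).

Two structural readings required a decision:

* CDKA/B:CYCB synthesis is repressed by unphosphorylated MYB3R3 through the
  saturating denominator,
  \(r_{cb,e2fb}\,E2FB/(k_{at}E2FB + V + k_{I}\,\mathrm{MYB3R3}_u)\), with
  \(k_I = 10\).  The alternative (an additive MYB3R3 term in the numerator)
  is incompatible with MYB3R3 acting as a repressor and with the monostable
  repression seen in the SMR-free submodel.
* SMR loses unphosphorylated mass at the slow basal rate and phosphorylated
  mass at the ten-fold faster CDK-marked rate; this differential decay is
  what lets rising CYCB collapse the SMR pool.

The reference implementation of the right-hand side is `cycle_rhs()` in R;
the production path is the identical C version (`src/cycle.c`) driven through
`deSolve`, and the two are compared term-by-term in the test suite at random
states.

## 2 Parameters and their provenance

`default_parameters()` ships the working constant set; the same values are
packaged as a flat `key = value` file under
`inst/extdata/default_parameters.conf`.  Most values follow the published
defaults for this network family (many of them inherited from an earlier
G1/S model).  Gaps and conflicts were resolved as follows:

* `kat_e2fa` and `kat_myb4` (saturation constants with no tabulated value)
  are set to `0.001`, the value every other saturation constant in the set
  takes.
* The MYB3R4 phosphorylation constant `kdp_cb1 = 0.125` takes the value
  tabulated in the MYB3R4 row (whose label collides with the SMR constant);
  the SMR constant keeps `kdp_cb2 = 0.25`.  The swapped assignment was also
  implemented and tested; it changes none of the qualitative results because
  all three G2/M phosphorylation readouts are gated by the same
  CYCB–SMR titration.
* CDKA:CYCD degradation includes an APC-mediated term with the tabulated
  `d_ca_apc = 0.5` (the SCF-mediated rate is tabulated as zero).  Without
  any ligase-mediated resetting of CDKA:CYCD the network cannot return to
  G1 and no limit cycle exists, so the tabulated constant is clearly meant
  to act.
* **E2FA abundance (`r_e2fa = 0.006`)**.  With synthesis and decay rates
  that would make the steady E2FA and RBR concentrations exactly equal, the
  G1/S subsystem is provably monostable: any RBR phosphorylation, plus the
  finite-affinity binding slack (\(\approx\sqrt{k_D T}\)), leaks free E2FA,
  which keeps FBL17 expressed, erodes KRP, and destroys both the bistable
  switch and every KRP-based size-control mechanism (inherited KRP would be
  degraded within a fraction of G1 instead of being diluted by growth).  All
  of the network's published behaviour — a bistable G1/S switch ended by a
  saddle-node, a sudden E2FA release, KRP persisting through G1 under
  phase-dependent synthesis, and strong G2/M size control — requires total
  E2FA to stay sub-stoichiometric to RBR so that free E2FA is fully
  sequestered until RBR phosphorylation passes the titration point.  We
  therefore set the E2FA synthesis rate to 0.006 (steady concentration 0.6
  against RBR's 1.0).  The viable window is narrow: below ≈0.0055 the
  repressed CYCB plateau can no longer clear the SMR threshold at zero
  growth and the limit cycle is lost; above ≈0.0075 the post-switch E2FB
  drive is strong enough that the G2/M transition stops waiting on SMR
  dilution and G2/M size control degrades.  This is the package's one
  deliberate deviation from the published constant table, and it is load
  bearing; it is flagged in `default_parameters()`'s documentation.

The growth rate `r_gr` is not a free constant: `calibrate_growth_rate()`
fixes it so that cells double in volume over one cycle,
\(r_{gr}=\ln 2/T\), where the period \(T\) is measured at the calibrated
rate itself (growth adds \(r_{gr}\) to every concentration's effective decay
rate, so \(T\) depends weakly on \(r_{gr}\)).  The fixed point is found by
iteration from the zero-growth limit-cycle period, to a relative tolerance
of \(10^{-4}\); the shipped default `r_gr = 6.5e-4` is this calibrated
value, and the test suite confirms both the doubling property and the
uniform-time-rescaling property (doubling all rate constants doubles the
calibrated growth rate).

## 3 Transitions, mitosis and division

The two checkpoints are detected on mechanistic readouts rather than
phenomenological size thresholds:

* **G1/S**: the first upward crossing of the *free-E2FA fraction*
  (free E2FA / total E2FA) through \(\theta_{E2FA}=0.5\).  Free E2FA is held
  near zero by RBR until CDKA:CYCD both titrates past KRP and phosphorylates
  enough RBR; the FBL17–KRP positive feedback then makes the release sharp.
* **G2/M**: the first upward crossing of the *phosphorylated-MYB3R4
  fraction* through \(\theta_{MYB4}=0.5\) after G1/S, driven by free
  CDKA/B:CYCB escaping SMR inhibition.

Both thresholds are configurable; because the switches are sharp, moving a
threshold from 0.4 to 0.6 moves the detected times by well under 5 % of the
period (asserted in the tests).  Events are located by the integrator's own
root finding (`lsodar`), so event times carry integration-level accuracy
rather than output-grid accuracy; crossings are made directional by staging
(a readout that starts above threshold — as in a freshly born, post-mitotic
cell — is first integrated down through it).

**Division is placed at the end of the mitotic program**, defined as the
MYB3R4 readout falling back through its threshold after the G2/M crossing,
rather than at the G2/M crossing itself.  The choice matters: the interval
between the two crossings is where MYB3R4-driven transcription happens —
the APC pulse that resets both cyclins, and (in the phase-dependent variant)
the KRP synthesis burst.  Dividing at the onset of mitosis would place that
burst *inside the daughters*, so each daughter would synthesise its own KRP
in proportion to its own size and equal inheritance of the mother's KRP
would be inert; dividing at the end of mitosis lets daughters inherit the
burst, which is the premise of the chromatin-bound-inhibitor hypothesis.
The G2/M checkpoint time and volume are still recorded at the up-crossing,
and the sizes reported at "G2/M" are checkpoint sizes.  An explicit
fixed-duration M phase is deliberately not added: mitosis already has a
finite duration here (the width of the MYB4 pulse).

At division the volume splits \(d:(1-d)\) with \(d\) drawn from a normal
distribution with mean ½, truncated to \((0,1)\) by rejection (clipping
would create atoms at the boundaries).  Proteins split in proportion to
volume — rapid post-breakdown diffusion homogenises concentration — except
proteins flagged *equally inherited*, which split exactly in half regardless
of \(d\), the limiting case of an inhibitor that rides the equally
partitioned chromatin.

The asymmetry scale \(\sigma_d = 0.05\) is not stated by the source
analysis; it was fixed once so that the stationary birth-size dispersion of
the well-controlled populations falls in the published 0.07–0.10 band
(quartile coefficient of dispersion), and is exposed in
`division_sampler()`.

## 4 Size-control hypotheses

`hypothesis_flags()` bundles the experimental switches:

* `size_independent`: any subset of KRP, RBR, MYB3R3, SMR synthesised at a
  constant (volume-independent) rate.  A size-independent inhibitor's mass
  is set by synthesis/decay balance while the activators scale with volume,
  so growth tips the balance — the inhibitor-dilution mechanism.
* `equal_inheritance`: proteins split equally at division.
* `krp_phase_dependent`: KRP's basal synthesis and decay are zeroed and its
  synthesis is driven by phosphorylated MYB3R4 at rate 0.05, confining
  production to late G2/M and early G1; KRP is then removed only by the
  FBL17 burst at G1/S, so within G1 its concentration falls purely by
  dilution.

Mechanistically, G1/S size control emerges because the switch fires when
the CDKA:CYCD concentration reaches a level offset by the KRP concentration;
a KRP pool whose mass does not scale with size (size-independent synthesis,
or an equally inherited birth allocation) makes that offset size-dependent.
G2/M control emerges because the MYB3R3-repressed CYCB production plateau
sits close to the SMR saddle-node: with size-independent SMR the transition
must wait for growth to dilute SMR to the plateau, making the G2/M timing a
near-sizer.  With every protein size-dependent the model is an almost
perfect timer — concentrations are size-invariant, so the cycle length
cannot depend on size and asymmetric division accumulates unboundedly.

## 5 Population engine and statistics

`simulate_population()` iterates the single-cell cycle over a binary lineage
tree with a continuous-time event queue ordered by birth time (ties broken
by cell id), so divisions are asynchronous and runs are bit-reproducible
under a fixed seed.  Defaults: stop after 8 mass-doubling times with a hard
cap of 4096 cells and a per-cell horizon of 4 doubling times; cells that
fail to divide within the stop time are recorded as incomplete and not
subdivided.  Statistics use completed cells only.  The analysis layer
provides the quartile coefficient of dispersion
(`qcd()`, \((Q_3-Q_1)/(Q_3+Q_1)\) with type-7 quantiles), OLS gradients
(`fit_slope()`), checkpoint-dispersion tables (`dispersion_summary()`,
`dispersion_panel()`), per-cell phase tables (`phase_scatter()`), and
simulated expression mutants (`mutant_experiment()`, ±50 %/−20 % on the
relevant synthesis rate).  `simulate_ideal()` supplies the closed-form
sizer/adder/timer reference populations.

The acceptance script and the test suite run populations for 9 doubling
times (one more than the engine default stop rule) so that every hypothesis
configuration — including the weakly controlled ones, whose cells are
slower — accumulates at least 200 completed cells per replicate; three
replicate seeds are averaged.  Generation-resolved spread statistics use
only fully populated generations, because generations truncated by the stop
time oversample fast lineages.

## 6 Bifurcation and robustness analysis

`bifurcation_scan()` isolates each checkpoint: the complementary module's
species are clamped to zero, volume is fixed (so mass equals concentration at
\(V=1\)), and the total kinase–cyclin concentration is treated as the
bifurcation parameter.  Clamping the **total** rather than the free kinase is
essential: the bistability lives in the feedback loop "inhibitor sequesters
kinase → less phosphorylation → inhibitor persists", and clamping the free
form severs it, leaving every subsystem trivially monostable.

At steady state all species are explicit functions of the feedback variable
(KRP at G1/S, SMR at G2/M), so all steady states are found by scanning the
1-D self-consistency residual on a 400-point log-spaced grid, refining each
sign change with `uniroot`, and deduplicating at \(10^{-6}\); stability comes
from the eigenvalues of the numerically differentiated reduced Jacobian
(5-D at G1/S, 3-D at G2/M).  This replaces arc-length continuation, which
would be overkill for fold-only diagrams of low-dimensional subsystems.
Saddle-node folds are reported where the branch count changes between
adjacent control values.  The SMR-free G2/M submodel (`"g2m_nosmr"`) retains
only MYB3R3 against the clamped kinase, and is monostable everywhere —
mutual inhibition alone does not make a switch; the stoichiometric
inhibitor does.  The zeroing convention keeps FBL17 dynamic inside the G1/S
subsystem: the KRP-high branch is destroyed precisely by the E2FA→FBL17
degradation loop, so removing FBL17 would remove the switch being analysed.

`limit_cycle_detect()` integrates the zero-growth model over 8000 time
units, discards the first 40 % as transient, and requires at least three
CDKA/B:CYCB peaks above an absolute floor (0.05) with peak-to-peak intervals
agreeing within 5 %; the period is the mean interval and is insensitive to
the output grid.  `robustness_scan()` applies this detector over log-spaced
one-at-a-time parameter grids spanning a factor of 10 each way;
`robustness_intervals()` extracts the cycling interval containing the
default.  The headline constraints — the CDKA:CYCD synthesis rate cannot be
too small, the KRP synthesis rate cannot be too large — are asserted in the
tests.

## 7 Numerical choices

* Integration: `lsoda`/`lsodar` (stiff-capable) with `rtol = 1e-8`,
  `atol = 1e-10`; the switches produce fast transients and the QSSA layer
  steepens the vector field near titration points.
* Slightly negative masses from integrator wiggle are clamped to zero inside
  the algebraic layer only; conservation closures (complex + free = total,
  phospho + unphospho = total) hold to \(10^{-9}\) relative and are tested.
* The binding quadratic is evaluated in its cancellation-free form and
  degenerate inputs (zero mass, zero \(k_D\)) short-circuit exactly.
* Event queue ties are broken by cell id; RNG state is saved and restored
  around seeded runs.
* Burn-in for the canonical founder: five symmetric-division cycles under
  the run's own hypothesis flags, starting from a uniform 0.1-mass state.

## 8 What the simulations do and do not emulate

The stochastic generator emulates exactly one noise source: division-plane
asymmetry.  Real dividing tissues additionally have expression noise,
cell–cell signalling, wall mechanics, hormone inputs, endoreduplication and
cell-cycle exit, none of which are modelled; mRNA dynamics are collapsed
into quasi-steady transcription kinetics, and the RNA-polymerase competition
account of why some genes are size-independent is summarised by the
indicator function rather than simulated.  Passing tests therefore show that
the *network logic* can generate size control and homeostasis under clean
exponential growth — not that these parameter values describe any particular
tissue.

## 9 Known limitations

* The constant set is a reconstruction: one constant (the E2FA synthesis
  rate) had to be moved off its published value to make the published
  qualitative behaviour (bistable switches, KRP dilution, homeostasis)
  reachable at all, and the working point was chosen inside a narrow viable
  window (section 2).  With this reconstruction the dispersion *pattern*
  across hypotheses is reproduced, but the G2/M stage compresses size
  variation more weakly than the published dispersion table (stage
  elasticity ≈0.8 versus ≈0.3–0.5), and the added-G1-volume gradients are
  correspondingly steeper; the corresponding acceptance checks fail and are
  intentionally left failing rather than re-tuned.
* The G1 phase occupies ~60 % of the cycle at the working point, which
  inflates G1-phase growth factors relative to the published figures.
* Only fold bifurcations are located; Hopf or more exotic structure, if
  any, would appear in the scans only as missing/flagged points.
* The idealised timer with symmetric division is structurally degenerate
  (volumes exactly preserved); tests treat it as an exact identity, not a
  statistical property.
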