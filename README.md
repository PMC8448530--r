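# neuroimpact

Computational biophysics of concussive closed-head injury in the mouse,
paired with a flow-cytometry neurodegeneration readout in *C. elegans*.
The package answers two questions that arise when studying why midbrain
dopaminergic neurons die after a non-invasive head impact:

1. **How much mechanical strain does a weight-drop impact deliver to brain
   regions far from the impact site?**  A plane-strain explicit-dynamics
   finite-element model simulates a sagittal mouse-brain section — six
   brain regions with published Prony-series viscoelastic parameters, a
   1.5 mm elastic skull shell, and a rigid brass/nylon impactor arriving at
   4.54 m/s — and records effective-stress / principal-strain time
   histories at monitor points in the cortex, thalamus, substantia nigra,
   cerebellum and brainstem.
2. **How much GFP fluorescence do sorted neuron populations lose after
   trauma?**  A large-particle flow-cytometry index turns per-worm
   fluorescence records into an injured/uninjured retention ratio,
   normalized to the empty-vector (EV) RNAi control, with quadrature error
   propagation across biological repeats.

It is aimed at researchers who want a reproducible, fully synthetic (no
external data) re-implementation of this pipeline that they can interrogate,
refit, or extend.

## The models in brief

Deviatoric stress in brain tissue follows the hereditary integral
τ(t) = ∫₀ᵗ G(t−s) γ̇(s) ds with a two-term Prony relaxation modulus

    G(t) = G0 (gL + g1 e^(−t/τ1) + g2 e^(−t/τ2)),

per-region parameters taken exactly from the published table (e.g.
thalamus G0 = 2674 Pa, cortex G0 = 6343 Pa), and an elastic volumetric
response with effective Poisson ratio 0.4995.  Dynamics use lumped-mass
central-difference integration of fully integrated plane-strain quads with
frictionless node-to-segment penalty contact; an energy ledger (kinetic,
stored, viscous-dissipated, contact storage) and a momentum audit run
alongside.  The GFP index is R = mean F(injured)/mean F(uninjured) per
sort, averaged over sorts, divided by the EV retention, with total error
sqrt(Σ(δX/(1−EV))² + SEM²between).

See the methods vignette (`vignettes/neuroimpact-methods.Rmd`) for the
full account, including the design decisions and known limitations.

## Worked example: the impact experiment

```r
library(neuroimpact)

cfg <- impact_config(geometry = geometry_spec(target_element_count = 1250))
res <- run_impact(cfg)
print(res)
```

```
<simulation_result> 73272 steps @ dt = 0.0546 us, status: completed
  energy residual 4.75e-06, momentum drift 4.41e-05, contact onset 0.19 ms
           monitor t_first_stress_ms first_stress_kPa max_strain arrival_order
1           cortex         0.2197839        1.3471235 0.09486089             1
2         thalamus         0.2397643        1.0826825 0.14439194             2
3 substantia_nigra         0.3296759        0.8989348 0.18632468             5
4       cerebellum         0.2397643        0.5682048 0.42481589             3
5        brainstem         0.2497545        0.3375183 0.20250833             4
```

Reading this: the impactor touches down at 0.19 ms (after its 0.9 mm
standoff flight); the stress wave reaches the cortex monitor first
(0.22 ms) and the deep substantia-nigra monitor ~0.11 ms later; peak
principal strains are 9.5% in the cortex but 19% in the substantia nigra
and 20–42% in the posterior monitors — deep regions are strained as much
as, or more than, tissue adjacent to the impact, which is the mechanical
basis for distal dopaminergic vulnerability.  The energy residual and
momentum drift certify the integration.  `plot(res$traces)` draws the
stress/strain histories; `peak_table(res)` gives the full peak table
including pressure-inclusive maximum principal stresses.

## Worked example: the cytometry index

```r
b <- simulate_sort(seed = 1)   # defaults: 1181 worms, 2 sorts, attenuation 0.579
r <- gfp_index(b, "EV")
print(r)
```

```
<gfp_index_result 'EV'> retention 0.5775 (42.3% loss), index vs EV = 1.0000 +/- 0.0359
```

The generator attenuated injured-worm fluorescence to 57.9% of control;
the pipeline recovers a 42.3% loss (true value 42.1%) with a propagated
error of 0.036.  `gfp_index_table()` evaluates every treatment in a batch
against the EV control, and `read_sort_batch()` ingests real CSV records
with columns `worm_id, fluorescence, condition, treatment, repeat_id`.

A command-line front end for both pipelines is installed at
`inst/scripts/impact.R` (`simulate`, `validate`, `peaks`, `gfp-index`,
`export-deck`).

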