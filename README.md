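# ibicg — Iterative Boltzmann Inversion for structure-based coarse-graining

`ibicg` derives coarse-grained (CG) pair force fields from target
structural distributions, the workflow used to coarse-grain peptides
adsorbing on carbon nanotubes: map all-atom configurations to
center-of-mass beads, measure radial / bond / angle distributions under
periodic boundaries, Boltzmann-invert them into potential-of-mean-force
tables, and refine the non-bonded table by running the package's own
tabulated-potential NVT molecular dynamics until the CG radial
distribution function matches the target. It is aimed at molecular
modellers who want a self-contained, fully scriptable IBI loop with a
compiled MD core, reproducible seeds, and plain-text file contracts.

## The method

With `g_target(r)` a target radial distribution function at temperature
`T`, the potential of mean force

    U0(r) = -kB T ln g_target(r)

initializes the fixed-point iteration

    U_{n+1}(r) = U_n(r) + kB T ln[ g_n(r) / g_target(r) ] + dU(r),
    dU(r) = alpha (1 - r/r_cut),   alpha = -0.001 kB T,

where `g_n` is measured from a CG simulation under `U_n` (leapfrog
integrator, canonical stochastic velocity-rescaling thermostat at
330 K, 1 nm cutoff). Convergence is scored by

    f_target = integral  e^{-r} ( g(r) - g_target(r) )^2  dr    (r in nm)

and iteration stops at `f_target <= 1e-4` or an iteration cap, keeping
the best-scoring iteration. Bond and angle potentials
(`U = -kB T ln P`, no Jacobian factors) are extracted once and never
iterated. By Henderson's theorem the pair potential reproducing a given
g(r) at a state point is unique up to a constant, so the fixed point is
well defined. All units are GROMACS conventions (nm, ps, amu, kJ/mol,
K; `kB = 0.0083144621 kJ/(mol K)`).

Because no reference all-atom ensembles are public, the package ships a
synthetic-reference module: toy (5,5) nanotube and capped-amino-acid
builders, and *closure fixtures* whose targets are generated by the
package's own engine under a known potential, so the whole inverse loop
can be validated end to end (see the methods vignette,
`vignettes/ibi-coarse-graining.Rmd`).

## Worked example: closing the loop on a known potential

```r
library(ibicg)

# target RDF generated by the engine itself under a known 12-6 table
# (160-bead supercritical LJ fluid, 150k-step run at 330 K)
fix <- make_closure_fixture("fluid", seed = 1, steps = 150000)

cfg <- ibi_config(max_iters = 100, f_tol = 1e-4, damping = 0.5,
                  smooth_window = 1L,
                  sim = sim_config(n_steps = 50000, sample_interval = 5),
                  base_seed = 100, iterate_pair = c("LJ", "LJ"))

fit <- run_ibi(fix$target, fix$system, cfg)   # starts from the PMF
print(fit)
summary(fit)
```

```
Iterative Boltzmann Inversion fit
  iterations run : 8 (cap 101)
  best iteration : 7 with f_target = 6.854529e-05
  converged      : yes (f_tol = 0.0001)
IBI fit summary
  iterations: 8, best: 7, converged: yes
  f_target: initial 2.9894e-03 -> best 6.8545e-05
  fitted well: -1.443 kJ/mol at r = 0.370 nm
  max |g - g_target|: 0.0395
```

Reading the numbers: the PMF alone misses the target by
`f_target = 3.0e-3` (it is exact only at infinite dilution); seven IBI
updates drive the weighted RDF mismatch below the `1e-4` tolerance.
The fitted well (-1.44 kJ/mol at 0.37 nm) recovers the ground-truth
12-6 table (well depth 1.5 kJ/mol before truncation shift, minimum at
2^{1/6} sigma = 0.38 nm) to well within thermal noise; the largest
pointwise RDF residual is about 0.04. `coef(fit)` returns the fitted
`(r, U, F)` table, `plot(fit)` draws RDF match, potential and
convergence history, and `simulate(fit)` runs CG MD under the fitted
potential. With `out_dir =` set, every iteration's potential and RDF
land in an `iter_NNN/` archive with a manifest that `read_archive()`
replays bit for bit.

A thin CLI wraps the same functions
(`inst/scripts/ibicg map|dists|pmf|simulate|ibi|fixtures`).

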