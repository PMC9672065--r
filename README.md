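# mshk — multistate machine-learned Hohenberg–Kohn maps

`mshk` learns the maps that density-functional theory guarantees exist but
never writes down.  The Hohenberg–Kohn theorem ties a molecule's external
potential $v(\mathbf r)$ — the Coulomb field of its nuclei — to its
electron density and, through it, to every observable including excited-state
energies.  This package learns those maps from data with kernel ridge
regression and uses them for excited-state molecular dynamics:

* **potential → density, per electronic state**: geometries become
  Gaussian-smeared potentials on a 3D grid
  ($v = \sum_a Z_a e^{-|\mathbf R_a - \mathbf r|^2/2\sigma_\mathrm{pot}^2}$,
  default 60×50×30 @ 0.2 Å, $\sigma_\mathrm{pot}=0.2$ Å); densities are
  Fourier-expanded, $n_j = \sum_l u_j^{(l)}\phi_l$ (default 50 modes/axis,
  125,000 functions), and each coefficient is a kernel expansion
  $u_j^{(l)}[v] = \sum_i \beta_{i,j}^{(l)} \kappa[v_i, v]$ with
  $\kappa[v_i,v] = \exp\!\big(-\tfrac{1}{\sigma^2}\int d\mathbf r\,(v-v_i)^2\big)$
  (note: no factor 2 in the denominator);
* **density → energy, one functional for all states** (ML-MSHK):
  $E[\,n_j\,] = \sum_{i,k} \alpha_{i,k}\,\kappa[\mathbf u_{i,k}, \mathbf u_j]$,
  trained on (geometry, state) pairs pooled across states, so the functional
  itself carries no state label;
* **potential → energy, state-specific** (ML-MSKS), the baseline that
  degrades near electronic crossings while the single multistate functional
  does not.

Around the maps sit the full workflow for studying excited-state
intramolecular proton transfer in a planar malonaldehyde-like system: the
training-set pipeline (Kabsch alignment to a C2v reference, mirror-plane
canonicalization enforcing $r_- = r_{\mathrm{HO}_1}-r_{\mathrm{HO}_2}\ge 0$,
K-means selection of 2500 samples under the L2-potential metric, reflection
doubling to 5000), an NVE velocity-Verlet / Langevin MD engine with
central-difference forces ($dx = 10^{-3}$ Å) and a planarity restraint
(9/40 kcal/(mol bohr²) on H/heavy atoms), and non-equilibrium observables:
the proton-location response function
$S(t) = \overline{\mathrm{sign}\,r_-(0)\,r_-(t)}$ with bootstrap confidence
bands, and the gating coordinate $\overline{d_{\mathrm{OO}}}(t)$.

Because ab initio reference data cannot be computed at desk scale, the
package ships a fully analytic **surrogate oracle**: a 9-atom C₃O₂H₄ model
with a state-dependent double well along $r_-$ whose separation is gated by
$d_{\mathrm{OO}}$ (S2 becomes barrierless below 2.45 Å), analytic forces,
and smooth atom-centred densities.  Every stage of the framework is
trainable and verifiable against its closed forms.  See the methods
vignette (`vignettes/mshk-methods.Rmd`) for the model, parameter choices,
and limitations.

## Worked example

```r
library(mshk)

## surrogate reference data: 100 ground-state frames + 2 excited-state
## trajectories (480 frames each, 0.25 fs) following vertical excitation
spec <- surrogate_spec()
ds <- generate_reference_dataset(spec, n_gs_frames = 100,
                                 n_es_trajectories = 2, seed = 7)
#> <surrogate_dataset> 1060 frames (100 gs + 960 es), seed 7

## training set: align, canonicalize, K-means-select 100, reflection-double
ts <- build_training_set(ds$geometries[ds$provenance$source == "gs"],
                         ds$geometries[ds$provenance$source == "es"],
                         spec$template, spec$permutation, k = 100, seed = 1,
                         clustering_grid = coarsen_grid(default_grid(), 4))
#> <training_set> 200 geometries (100 selected x 2 by reflection)

## train the two maps
basis <- basis_spec(default_grid(shape = c(40, 34, 20), spacing = 0.3),
                    c(13, 13, 13))
pot_grid <- coarsen_grid(default_grid(), 2)
ref <- attach_reference_data(ts$geometries, spec, basis)
x <- potential_matrix(ts$geometries, pot_grid, sigma_pot = 0.2)
dmap <- train_density_map(x, ref$coefficients,
                          sigma = median_heuristic(x), lambda = 1e-8)
efun <- train_energy_functional(ref$coefficients, ref$energies,
  sigma = median_heuristic(do.call(rbind, ref$coefficients)) / 2,
  lambda = 1e-8)
model <- mshk_model(dmap, efun, spec$template, pot_grid, basis,
                    sigma_pot = 0.2)

## per-state energies for an unseen thermal geometry (kcal/mol)
g <- canonicalize(ds$geometries[617], spec$template,
                  spec$permutation)$geometries[[1]]
predict_mshk(model, g)$energies
#> ML-MSHK : S0 7.655   S1 108.999  S2 128.827
surrogate_energies(spec, g)
#> exact   : S0 7.517   S1 109.325  S2 129.346
```

The S1/S2 offsets (~100 and ~122 kcal/mol) are the surrogate's vertical
excitation energies; a 200-sample model already predicts all three states
of an out-of-sample geometry to a few tenths of a kcal/mol.

Excited-state dynamics and the proton-transfer observables:

```r
inits <- vertical_excitation_initial_conditions(ds$gs_trajectory, 100, 2)
trajs <- lapply(inits[1:8], function(st)
  velocity_verlet_run(surrogate_surface(spec, 2), st, dt = 0.25,
                      n_steps = 240, restraint = restraint_spec()))
rf <- response_function(trajs, n_resamples = 999, seed = 1)
#>    t     S   lo   hi
#>    0  1.00  1.0 1.00
#>   20  0.25 -0.5 0.75
#>   40 -0.25 -1.0 0.50
#>   60  0.25 -0.5 1.00
mean_distance_series(trajs)
#> mean d_OO: t=0: 2.587   t=30fs: 2.414
```

$S(0)=1$ (every trajectory starts in its reactant basin) and decays toward
0 as transfers complete, while the ensemble-mean O–O distance contracts
from ~2.59 to ~2.41 Å in the first 30 fs — the heavy-atom gating motion
that unlocks the proton transfer.  With 8 trajectories the 95% bootstrap
bands are wide; the production protocol uses hundreds.

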