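# mbo3d — manifold-based 3D genome reconstruction from single-cell Hi-C

Single-cell Hi-C yields, per cell, a sparse binary contact map: for a
chromosome binned into `n` fixed-width intervals, a symmetric matrix `C` with
`C_ij = 1` where bins `i` and `j` were caught in contact. `mbo3d`
reconstructs the underlying 3D bead-chain structure from such a map — a
Euclidean distance matrix (EDM) completion problem, since the contacts
constrain only a small fraction of the pairwise distances.

The method:

1. **Target distances** — contacts become `d_c = 60` nm, consecutive bins
   without a contact `d_n = 120` nm (a contact between neighbors wins).
2. **Shortest-path completion** — every other pair gets the length of the
   shortest path over the observed edges, with the hop count `n_ij` of that
   path recorded.
3. **Hop-count weights** — `H_ij = n_ij^(-q)`: observed pairs keep weight 1,
   imputed distances are trusted less the further their information
   travelled; `q` is chosen by grid search.
4. **Manifold optimization** — minimize the weighted square-root stress

   ```
   f(X) = 1/2 || H ⊙ ( sqrt(κ(XXᵀ)) − sqrt(D) ) ||²_F ,   κ(B) = b eᵀ + e bᵀ − 2B
   ```

   over rank-3 Gram factors `X ∈ R^{n×3}` (the fixed-rank positive
   semidefinite quotient manifold), with a Riemannian trust-region solver
   using the exact analytic gradient and Hessian.
5. **Rescale and score** — a bisection scale factor `c_l` makes the structure
   reproduce exactly the observed contact count; the report gives % correct
   contacts, % minimum-distance violations (< 30 nm) and % connectivity
   violations (consecutive beads > 200 nm).

A classical-MDS baseline (`cmds_reconstruct()`, shortest-path completion +
spectral embedding) and a full simulation harness (synthetic chains,
multiplicative noise on squared distances, uniform deletion, noise/sparsity
grids, reconstruction-limit curves) are included. See the vignette in
`vignettes/manifold-reconstruction.Rmd` for the model, numerical choices and
their rationale.

## Worked example

```r
library(mbo3d)

## synthetic ground truth: a 120-bead chain, and a single-cell-like map
## (candidate contacts within 250 nm, subsampled to 110 = 0.9 per bin)
chain <- generate_chain(120, step_nm = 120, smoothness = 0.4, seed = 20)
cmap  <- sample_contacts_from_structure(chain, d_c = 250,
                                        target_contacts = 110, seed = 21)

run <- reconstruct_chromosome(cmap, q = 2,
                              cfg = mbo_config(seed = 1, dist_tol = 1e-2))
run$report
#> reconstruction report
#>   contacts (n_c):            110
#>   % correct contacts:        94.55
#>   % min-distance violation:  0.000
#>   % connectivity violation:  0.000
#>   scale factor c_l:          0.810302
#>   q used:                    2

reconstruct_chromosome(cmap, method = "cmds")$report$pct_correct_contacts
#> [1] 21.81818
```

Read: the weighted manifold reconstruction re-establishes 94.5% of the
observed contacts with no bead pair closer than 30 nm and no chain break
longer than 200 nm, while the classical-MDS baseline recovers only ~22% of
the same map. `write_coords()`, `write_bead_pdb()` and `write_report_json()`
export the structure and report; the thin CLI at `inst/scripts/mbo3d`
(subcommands `reconstruct`, `simulate`, `benchmark`, `evaluate`) drives the
same functions from a shell.

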