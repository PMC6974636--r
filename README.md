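# lantimass

Modification-aware mass bookkeeping for cross-linked lanthipeptides.

Type B lantibiotics of the cinnamycin family (kyamicin, cinnamycin,
duramycin) are 19-residue peptides carrying three thioether bridges, a
lysinoalanine cross-link and a β-hydroxylated Asp15. Their identification in
culture extracts — and the confirmation of their connectivity — rests on a
chain of mass-spectrometric arithmetic: derive the elemental formula from
the modified structure, predict multiply protonated m/z values, follow the
chemical-reduction species ladder, read the y-ion fragment series of the
desulfurised peptide, and annotate observed peaks within a ppm tolerance.
`lantimass` implements that chain for anyone screening heterologous hosts or
new family members.

The core arithmetic, for a structure with *n* dehydrations, *h*
hydroxylations and *b* thioether bridges:

```
mature   = linear(core) − n·H2O + h·O        (bridging is mass-neutral)
reduced_k = mature − k·S + 2k·H              (k = 0..b, NiCl2/NaBH4)
[M + zH]z+ = (M + z·1.007276466621) / z      (proton, not H-atom, mass)
ppm = (observed − calculated)/calculated × 1e6
```

Fragmentation at the lysinoalanine bridge is modelled as the observed
rearrangement: the Dha-derived donor reads as glycine and the Lys acceptor
keeps the bridge carbon as N=CH2 (lysine + C), an atom-conserving split, so
complementary y-ion fragments always sum to the precursor composition.

## Worked example

```r
library(lantimass)

ky <- kyamicin_structure()          # packaged YAML structure config
render_formula(mature_formula(ky))
#> [1] "C76H108N20O25S3"
format_mz(ion_mz(mature_formula(ky), 2))   # [M+2H]2+
#> [1] 899.3551

reduction_series(ky)                # the desulfurisation ladder at z = 2
#> # A tibble: 4 × 5
#>       k species        formula         charge    mz
#>   <int> <chr>          <chr>            <int> <dbl>
#> 1     0 kyamicin       C76H108N20O25S3      2  899.
#> 2     1 kyamicin (-1S) C76H110N20O25S2      2  884.
#> 3     2 kyamicin (-2S) C76H112N20O25S       2  869.
#> 4     3 kyamicin (-3S) C76H114N20O25        2  854.

# screen an observed peak list for mature kyamicin
rep <- screen_species(data.frame(mz = c(899.3553, 450.2)), ky, tol_ppm = 10)
tidy(rep)[, c("species", "mz", "mz_obs", "ppm", "detected")]
#> # A tibble: 1 × 5
#>   species     mz mz_obs   ppm detected
#>   <chr>    <dbl>  <dbl> <dbl> <lgl>
#> 1 kyamicin  899.   899.  0.21 TRUE
```

The m/z columns are monoisotopic; 899.3551 is the doubly protonated mature
kyamicin ion, and the 0.21 ppm error says the observed peak is within
instrument accuracy of the prediction, i.e. a detection at the default
10 ppm tolerance. `y_ion_ladder(ky)` gives the 18-member fragment series of
the reduced peptide, `simulate_peaklist()` generates synthetic peak lists
with known ground truth, and `autoplot()` works on match reports and
ladders. A thin command-line wrapper with `predict`, `reduce`, `fragment`,
`annotate` and `simulate` subcommands lives at
`inst/scripts/lantimass.R`.

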