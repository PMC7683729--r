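# deerscape

Conformational-state analysis of hinged, two-domain proteins from Gd(III)
DEER spectroscopy, structure-based spin-tag modelling, trajectory
classification and enzyme kinetics.

## The problem

Solute-binding-protein (SBP) folds consist of two domains joined by a
flexible hinge; their function depends on how they partition between
*closed*, *open* and *wide-open* states. Double electron–electron resonance
(DEER/PELDOR) with rigid Gd(III) tags measures the distance distribution
between two labelled sites and therefore reports that partition directly in
frozen solution — provided one can (i) predict where the Gd ion sits when a
propargyl-DO3A-Gd(III) tag is modelled onto a structure, (ii) invert the
measured dipolar time trace into a distance distribution with honest
uncertainty, (iii) map simulation snapshots and measured distributions onto
state windows, and (iv) handle the statistics of partially tagged oligomers
and the enzyme-kinetics arithmetic that frames the biology. `deerscape`
implements that chain for R, with synthetic-data generators so every stage
runs and is testable without any external download.

## The core model

The intramolecular DEER signal for a distance distribution *p(r)* is

    V(t) = (1 − λ + λ ∫ K(t, r) p(r) dr) · exp(−(k t)^(d/3))

with modulation depth λ, stretched-exponential intermolecular background
(rate *k*, dimension *d*), and the weak-coupling dipolar kernel

    K(t, r) = ∫₀¹ cos( 2π (D / r³) (1 − 3z²) t ) dz,   D = 52.04 MHz nm³.

Inversion solves `min ‖K p − F‖² + α² ‖L p‖²` subject to `p ≥ 0` (L = second
difference), with α chosen at the maximum-curvature corner of the L-curve,
a joint re-fit of (λ, k) given the inverted dipolar shape, and a validation
band (mean ± 2 s.d. over background/noise perturbations). Tag positions come
from a rigid rotamer model of the AzF + triazole + DO3A-Gd arm: χ1/χ2 from a
least-clash grid scan, χ6 = 180°, χ9 = −140°, χ10 = 70° (single-conformer
mode) or χ9 free × χ10 ∈ {−60°, 60°, 180°} (ensemble mode). Trimer
tag-dilution follows the binomial law `C(3,k) p^k (1−p)^(3−k)`; catalytic
efficiency errors propagate as
`SE = (kcat/KM) · sqrt((SE_KM/KM)² + (SE_kcat/kcat)²)`.

## Worked example

```r
library(deerscape)

# simulate the bimodal closed/open situation: peaks at 3.2 and 4.4 nm
truth <- deer_ground_truth(means = c(3.2, 4.4), sds = c(0.15, 0.15),
                           weights = c(0.5, 0.5), snr = 50, seed = 1)
ds  <- make_deer_dataset(truth)
ana <- deer_analyze(ds$trace)          # background fit + L-curve inversion
summarize_distribution(ana$distribution)
#> $peaks   [1] 3.2 4.4        # both maxima recovered on the 0.02 nm grid
#> $mean    [1] 3.79           # mean distance, nm
ana$lambda
#> [1] 0.399                   # modulation depth (truth: 0.4)

# classify a synthetic 5000-frame trajectory with occupancies (0.2, 0.3, 0.5)
defs <- state_definitions(c("closed", "open", "wide-open"),
                          ca_lo = c(2.4, 3.1, 3.9), ca_hi = c(3.0, 3.8, 4.6))
st <- data.frame(name = defs$name, ca_mean = c(2.7, 3.45, 4.25),
                 ca_sd = 0.06)
P  <- 0.65 * diag(3) + 0.35 * matrix(c(0.2, 0.3, 0.5), 3, 3, byrow = TRUE)
traj <- make_trajectory(trajectory_spec(st, P, n_frames = 5000, seed = 1))
populations_from_trajectory(classify_snapshot(traj$ca_nm, defs), defs)
#> <state_populations>
#>   closed     0.199
#>   open       0.312
#>   wide-open  0.490

# tenfold tag dilution of a trimer
trimer_tag_mix(0.1)
#> <trimer_tag_mix> tagged fraction 0.100
#>   k=0: 72.9%   k=1: 24%   k=2: 3%   k=3: 0.1%

# catalytic efficiency with propagated error (KM in uM, kcat in 1/s)
efficiency(mm_fit_values(18.7, 2.9, 18.4, 0.7))
#> $value [1] 983957.2         # ~9.8e5 1/(M s)
#> $se    [1] 157116.7         # ~1.6e5
```

The peak positions bracket the closed and open states of the hinge; their
~1.2 nm separation is what makes the two states resolvable in a 4 µs trace.
The state populations recover the generating Markov occupancies to ~0.01,
and the binomial table shows why tenfold dilution isolates singly tagged
trimers (24% singly vs 3% doubly tagged).

Per-protein state windows (Cα–Cα and Gd–Gd, in nm) ship in
`inst/extdata/state_definitions.yaml` and load with
`load_state_definitions("AncCDT-1")` etc. A complete configuration-driven
run is available through `run_pipeline()` (see `?run_pipeline`) or the thin
CLI in `inst/scripts/deerscape`.

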