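# mtseam

Quantitative tools for microtubule lattice architecture and dynamics,
aimed at structural biologists working on the ciliary tip central pair
and on seam-binding microtubule-associated proteins (MAPs), and at
single-molecule groups quantifying dynamic instability from TIRF
kymographs.

A microtubule is a tube of N protofilaments (PFs). In the canonical
B-lattice, lateral contacts are homotypic (α–α, β–β) everywhere except
one junction — the seam — where the helical pitch of 1.5 dimers forces
an α–β contact. `mtseam` covers three linked analyses around this
geometry, each paired with a synthetic-data generator so the entire
pipeline runs without any external data:

1. **Lattice geometry.** Parametric N-PF lattices with full ground
   truth (`mt_lattice`); the inter-PF angle statistic — the central
   angle between adjacent PF centers about a least-squares circle fit
   in the cross-section, averaged over axial repeats
   (`compute_inter_pf_angles`; for an ideal tube every junction is
   360/N); coordinate-based seam detection by nearest lateral
   neighbour chain parity (`classify_junctions`); angular clustering
   of unlabelled coordinates (`assign_protofilaments`).
2. **Tomographic volumes.** Synthetic decorated-microtubule densities
   with a ±60° missing wedge (`render_lattice_volume`,
   `apply_missing_wedge`); 8-nm filament picking grids
   (`interpolate_filament_grid`); PF-number classification from the
   rotational power spectrum of the annulus, read off the 4-nm layer
   line where the information survives the wedge
   (`classify_pf_number`); per-junction scoring of 8-nm-periodic
   external decoration and seam-binder calling
   (`junction_decoration_profile`, `call_seam_binder`).
3. **Dynamic instability.** A continuous-time two-state simulator
   (growth at v_g, shrinkage at v_s, catastrophe f_cat, rescue f_res,
   nucleation k_nuc) sampled at the movie frame rate
   (`simulate_dynamics`), TIRF-style kymograph rendering
   (`render_kymograph`), and the kymograph quantification chain:
   tip tracing (`trace_tip`), phase segmentation (`segment_phases`),
   first-triangle dynamic parameters (`compute_dynamics_summary`),
   the 5-pixel rescue rule (`classify_rescue`,
   `rescue_probability`) and dose–response aggregation
   (`aggregate_conditions`).

Standard formats are supported throughout: PDB/mmCIF and CSV for
coordinates, MRC (mode 2) for volumes, TIFF (+ JSON calibration
sidecar) for kymographs, IMOD ASCII point exports and CSV for traces.

## Worked example

```r
library(mtseam)

lat <- mt_lattice(n_pf = 13, n_repeats = 6)
lat
#> Microtubule lattice: 13 PFs x 6 dimer repeats (156 monomer sites)
#>   radius 11.00 nm, dimer rise 8.0 nm, start stagger 12.0 nm
#>   seam at junction (13, 1), closing mismatch 4.00 nm

jt <- classify_junctions(lat)
jt[jt$is_seam, ]
#>    pf_i pf_j lateral_pairing axial_offset is_seam
#> 13   13    1     heterotypic    0.9230769    TRUE
```

The 12-nm start stagger leaves a half-dimer (4 nm) mismatch at the
closing junction, so exactly one junction is heterotypic: the seam,
between PF 13 and PF 1. The homotypic junctions carry the per-PF
helical stagger of 12/13 ≈ 0.92 nm.

```r
v <- render_lattice_volume(lat, decorations = data.frame(junction = 13),
                           voxel_size = 8, snr = 0.5, wedge = 60, seed = 1)
classify_pf_number(v)
#> $n_pf
#> [1] 13
#> $scores
#>        13        14
#> 31.112428  8.651219
#> $margin
#> [1] 22.46121

call_seam_binder(junction_decoration_profile(v, lat))
#> $junction
#> [1] 13  1
#> $unique
#> [1] TRUE
```

Even at SNR 0.5 under a ±60° missing wedge, the rotational spectrum
picks 13 over 14 PFs with a wide margin, and the 8-nm-periodic
external density is called at the seam junction only — the signature
of a seam-binding MAP.

```r
tr <- simulate_dynamics(di_params(), seed = 5)
ky <- render_kymograph(tr, psf_sigma = 1, snr = 5, seed = 12)
compute_dynamics_summary(segment_phases(trace_tip(ky)))
#>   length_um lifetime_min growth_rate shrink_rate nucleation_time_min censored
#> 1       1.6     1.166667    1.164286          NA            6.833333    FALSE
```

The recovered growth rate (1.16 µm/min) sits close to the simulated
1.2 µm/min; this particular first triangle collapsed in under three
frames, so its shrinkage rate is reported as missing (`NA`) rather
than as an unreliable two-point slope. Rescue events carry the 5-pixel
rule: regrowth more than 5 px from the seed is a true rescue.

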