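# fabricgait

Trabecular bone adapts to habitual loading: struts align their long axes
along the trajectories of peak compressive stress. In the distal tibia, the
**principal trabecular orientation (PTO)** just deep to the ankle joint
surface therefore records the posture in which the joint was habitually
loaded — extended versus flexed ankles leave measurably different fabric.
`fabricgait` implements the full analysis chain that links the two ends of
this inference, for researchers in skeletal biomechanics and biological
anthropology:

- **Fabric analysis** by the mean-intercept-length (MIL) method.
  MIL(**n**) = total test-line length / number of bone–non-bone interface
  crossings along direction **n**. In 2D the sagittal-plane PTO is the angle
  α of the largest-MIL direction measured from the line normal to the bone
  long axis (α = 90° ⇔ PTO parallel to the long axis). In 3D the fabric
  tensor **H** is fitted by least squares to **n**·**H**·**n** = 1/MIL(**n**)²
  over a 257-direction hemisphere set; eigenvalues h₁ ≤ h₂ ≤ h₃ give MIL
  semi-axes MILᵢ = 1/√hᵢ, the PTO axis (eigenvector of h₁) and the degree of
  anisotropy DA = MIL₁/MIL₃ ≥ 1.
- **Morphometry** for spherical volumes of interest (VOIs): BV/TV (exact
  voxel counting), Tb.Th and Tb.Sp (largest-fitting-sphere local thickness of
  bone and background), Tb.N = (BV/TV)/Tb.Th, and ConnD from the Euler
  characteristic of the cubical complex (β₁ ≈ 1 − χ per VOI volume).
- **Directional statistics**: axes with antipodal identification,
  longitude/latitude and equal-angle (Wulff) stereoplot coordinates
  (radius = tan((90° − latitude)/2)), haversine great-circle distances,
  spherical centroids, an exhaustive/Monte-Carlo **median permutation test**
  for 2D angles, a **haversine-centroid permutation test** for 3D axes, and
  an exact (dynamic-programming) two-sided Wilcoxon rank-sum test.
- **Gait kinematics**: zero-lag 4th-order Butterworth filtering, the
  four-landmark ankle angle (femoral epicondyle–malleolus line versus
  calcaneus–5th-metatarsal line, lateral view), the peak-loading window
  (GRFv > 75 % body weight, possibly two intervals for double-peaked walking
  traces), the mean ankle angle over that window, and the Froude number
  v²/(gL).
- **Synthetic data with exact ground truth**: jittered rod lattices and
  thresholded anisotropic Gaussian random fields with a prescribed fabric
  axis and BV/TV, analytic phantoms for the thickness and topology oracles,
  Watson-distributed axis samples, and double-peaked gait trials with a
  prescribed ankle-angle profile.
- **Pipeline**: `run_specimen()` / `run_study()` / `run_demo()` orchestrate
  specimens → VOIs → fabric + morphometry → group statistics, emitting a
  per-VOI parameter table, a stereoplot coordinate table (specimen, side,
  longitude, latitude) and a replayable JSON statistics ledger. Volumes
  travel as uncompressed multi-page TIFF stacks (bone = 255, background = 0)
  with a plain-text spacing sidecar; gait trials as CSV.

## Worked example

```r
library(fabricgait)

# a synthetic "specimen": trabecular struts tilted 7.7 degrees anteriorly
v   <- make_rod_lattice(rod_lattice_spec(shape = c(96, 96, 96),
                                         primary_axis = c(-sin(7.7*pi/180), 0,
                                                          cos(7.7*pi/180)),
                                         seed = 3))
voi <- extract_voi(v, spherical_voi(c(47.5, 47.5, 47.5), diameter = 40))

# sagittal-plane 2D-PTO from the 10 middle sagittal slices
pto_2d(mil_profile_2d(middle_sagittal_slices(voi$volume),
                      middle_sagittal_slices(voi$mask)))
#> 2D-PTO: alpha = 97.50 deg, in-plane anisotropy = Inf

# 3D fabric tensor in the spherical VOI
fabric_voi(voi$volume, voi$mask)
#> Fabric: DA = 11.283, PTO = (-0.140, 0.021, 0.990) [lon 171.4, lat 81.9],
#>         residual 0.182

# ankle angle at peak loading from a synthetic walking trial
tr <- make_gait_trial(gait_trial_spec(angle_profile = function(s) 85.6))
mean_angle_at_peak_loading(tr, filter = FALSE)
#> [1] 85.6
#> attr(,"coverage")
#> [1] 0.4792013
#> attr(,"n_intervals")
#> [1] 2
```

The recovered α of 97.50° is within a quarter degree of the constructed
97.7° tilt; the 3D PTO axis is within 1.4° of the generator's axis (an
uncrossed rod lattice is almost perfectly anisotropic, hence the extreme DA
and the in-plane anisotropy reported as infinite); the constant-angle trial
is recovered exactly over a peak-loading window covering 48 % of stance in
two intervals. A full miniature study (two
"species" groups of 6 plus a group of 3 at the first group's orientation,
with permutation tests and pooled-group comparisons) runs with

```r
run_demo("demo_out", seed = 1)
```

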