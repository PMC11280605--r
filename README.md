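# cestrecon

Joint k-ω reconstruction and Z-spectrum fitting for CEST MRI, in R.

CEST (chemical exchange saturation transfer) MRI measures one image per
saturation offset frequency ω and reads out dilute-solute contrast from the
pixel-wise Z-spectrum `Z(x,ω) = f(x,ω)/f(x,ω0)`, usually via the MTR
asymmetry `MTRasym(ω) = [S(−ω) − S(+ω)]/S0`. The conventional pipeline
reconstructs every frame independently (inverse FFT) and fits spectra pixel
by pixel afterwards, so frame noise lands directly in the asymmetry maps.

`cestrecon` implements both that baseline and a joint reconstruction that
estimates the amplitude images at all offsets simultaneously:

    min over {f, A, Z}   1/2 Σ_ω | F A(x,ω) f(x,ω) − g(ω) |²  +  R[f, λ]
    subject to           f(x,ω) = f(x,ω0) · Z(x,ω)

with `F` the unitary centred 2D Fourier transform, `A = exp(iφ)` the phase
factors, `R` a spatial prior applied through a plug-and-play denoiser, and
`Z` constrained to a multi-pool model — a Lorentzian water line plus
Gaussian CEST pools at known centres ω_i:

    Z(ω) = 1 − a/((ω−ω1)² + Γ) − Σ_i b_i · exp[−(ω−ω_i)²/σ_i²]

The problem is solved by ADMM: CGLS image updates (the reference-image
update couples information from all offsets), batched pixel-wise bounded
Levenberg–Marquardt for the spectral projection, plug-and-play denoising
with an adaptively estimated strength (half the mode of local 5×5 patch
variances), a closed-form auxiliary-spectrum update, and dual ascent.
A compartment phantom simulator (Fourier encoding, complex Gaussian k-space
noise scaled to the mean reference-frame magnitude, offset subsampling) and
SNR / MTR-asymmetry evaluation utilities complete the pipeline.

## Worked example

```r
library(cestrecon)

scene <- build_phantom("simulated_brain", shape = c(64, 64))   # 51 offsets,
                                                               # pool at 450 Hz
sim   <- simulate_acquisition(scene, noise_level = 0.105, seed = 7)
conv  <- conventional_reconstruct(sim$kspace)
joint <- joint_reconstruct(sim$kspace, cfg = recon_config(max_outer_iters = 10))

rois <- scene$roi_masks
averaged_snr(conv$images,  rois$cest_roi | rois$tissue, rois$background)$averaged_db
#> [1] 35.82852
averaged_snr(joint$images, rois$cest_roi | rois$tissue, rois$background)$averaged_db
#> [1] 61.21656

st_c <- roi_statistics(mtr_asymmetry_map(conv$images, 450),
                       rois[c("cest_roi", "tissue")])
st_j <- roi_statistics(mtr_asymmetry_map(joint$images, 450),
                       rois[c("cest_roi", "tissue")])
st_c$sd
#> [1] 0.02830519 0.02327180
st_j$sd
#> [1] 0.002319285 0.002292131
uncertainty_reduction(st_c$sd, st_j$sd)$reduction_pct
#> [1] 91.05916
```

At 10.5% k-space noise the joint method lifts the frequency-averaged SNR
from ~36 dB to ~61 dB on this phantom and shrinks the within-ROI standard
deviation of the 450-Hz MTR-asymmetry map by an order of magnitude —
the same qualitative behaviour at every noise level from 10.5% to 25%, and
under a 27.5% reduction in the number of acquired offsets (the insert's
asymmetry stays clearly detectable where the baseline's contrast-to-noise
collapses). The true insert asymmetry is 0.10; both methods centre on it,
the joint method with far less spread.

A thin command-line interface over the same functions lives at
`inst/cli/cest.R` (`simulate`, `reconstruct`, `evaluate`, `fit`
subcommands, YAML configs, NIfTI+JSON containers).

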