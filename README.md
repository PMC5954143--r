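# chromashift

Correction of three-dimensional chromatic shift between the color
channels of fluorescence microscopy images, without fiducial markers.

Multicolor imaging assumes the channels are geometrically aligned, but
dispersion in the optics and in the specimen displaces the channels
relative to each other by tens to hundreds of nanometres — often more
than the resolution of super-resolution microscopes.  Bead-based
calibration measures the optics, not the sample.  `chromashift`
estimates the correction directly from a biological reference image
(any structure visible in both channels, e.g. through spectral
bleed-through), so the measured shift includes the sample's own
dispersion.

## The method

The distortion of a subject channel relative to the reference channel is
modelled as a seven-parameter global affine transform — translation
(T_X, T_Y, T_Z), per-axis magnification (M_X, M_Y, M_Z) and rotation
about the optical axis (R_Z) — optionally refined by a dense elastic map
of residual local translations.

**Quadrisection phase correlation.**  Phase correlation whitens the
spectra of the two images,

    P̃(λ, u, v) = G(u, v) S̃(λ, u, v) / |S̃(λ, u, v)| ,
    R(x, y)    = F⁻¹[ P̃(1, u, v) P̃*(2, u, v) ] ,

with G a Gaussian frequency mask (SD 0.2 of the Nyquist frequency), and
reads the relative translation off the correlation peak.  Measuring this
peak separately in the four quadrants of the field yields four
displacement vectors **a**–**d**; summing a diagonal pair cancels the
rotation and magnification parts and leaves the translation
(T = ((a+c)/2 + (b+d)/2)/2), while the half-differences of the pairs
split into a tangential component (the rotation angle, via its
arctangent over the quadrant radius) and a radial component (the
per-axis magnification, via the edge displacement M as (M + c)/c).
Lateral parameters come from the z-projection, axial ones from the
x-projection; the cycle is iterated to below 1 nm and polished by a
final plain 3D cross correlation.

**Local elastic refinement.**  After global alignment the images are
split into tiles (4×4, then halving the window down to 60 px), the
per-tile phase-correlation shift is measured on an interleaved
half-offset grid, gated by a variance threshold (v = 0.1·var(S₁)·var(S₂)
against the central-quarter tile variance) and a correlation-peak floor
of 0.02, gap-filled with a growing mean filter, and Fourier-upsampled to
a dense map L(x, y) that is added to the affine coordinate map A(x, y).

**Real-space conversion.**  Rotation and magnification are expressed as
the displacement they induce at an image-edge coordinate (the edge-pixel
rule; e.g. a 0.5° rotation moves the edge point (1024, 512) of a
1024-wide image to (1023.98, 516.47), a deviation of (0.02, −4.47) px),
and the total deviation is the Euclidean vector sum over the seven
parameters times the pixel size.

## Worked example

```r
library(chromashift)

# a two-channel synthetic reference: filaments, with a known chromatic
# shift induced on channel 2
ref   <- sim_filaments(c(16, 256, 256), n_filaments = 30, seed = 1)
shift <- affine_params(t_x = -2, t_y = -3, m_x = 0.998, m_y = 0.999,
                       r_z = 0.5)
sub   <- induce_affine(ref, shift)
arr   <- array(0, c(1, 2, dim(ref)))
arr[1, 1, , , ] <- ref
arr[1, 2, , , ] <- sub

fit <- chromashift(multichannel_image(arr, pixel_size_nm = c(78, 78, 125)))
fit
#> Chromatic-shift registration fit
#>   reference channel 1; 16 z x 256 y x 256 x px; pixel 78/78/125 nm
#>   channel_2 (converged, 5 iterations):
#>     t = (-2.006, -3.008, -0.001) px, m = (0.99832, 0.99910, 1.00000), r_z = 0.4985 deg

summary(fit)
#> Real-space chromatic shift per channel (nm, edge-pixel rule):
#>    channel    t_x    t_y  t_z   m_x  m_y m_z   r_z total_2d  total
#>  channel_2 156.45 234.65 0.08 16.77 9.03   0 86.86   295.71 295.71
```

The fitted translation (−2.006, −3.008) px, magnification
(0.99832, 0.99910) and rotation 0.4985° recover the induced values to a
few hundredths of a pixel.  The summary converts each parameter into the
real-space displacement it causes at the image edge: here the channel
was off by ~296 nm in total before correction.  `predict(fit, target)`
applies the correction to any target image (translations rescale with
target size; rotation and magnification are scale-free), and
`chromashift(..., local = TRUE)` adds the elastic map.  Lower-level
functions (`estimate_global()`, `refine_local()`, `apply_affine()`,
`logpolar_estimate()`, `simplex_estimate()`, `fit_beads_3d()`, ...) expose
each stage; `inst/scripts/chromashift` is a command-line front end with
`measure`, `apply`, `simulate` and `benchmark` subcommands.

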