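# srrmri

Super-resolution reconstruction (SRR) of an isotropic high-resolution MRI
volume from multiple fast, anisotropic thick-slice stacks acquired with
variable slice-selection directions (axial / coronal / sagittal). The
target users are imaging researchers who need high through-plane
resolution at short scan times — the motivating application is neonatal
brain MRI, where direct high-resolution acquisition is too slow and too
noisy — and who want a self-contained, testable implementation of the
whole chain: acquisition forward model, registration, reconstruction,
baselines, and quality assessment, exercised end-to-end on a synthetic
phantom with known ground truth.

## The model

Each low-resolution stack is modelled as

    y_k = D_k H_k T_k x + e_k,   k = 1..n

with `x` the HR volume, `T_k` a 6-DOF rigid inter-scan motion, `H_k` a
Gaussian slice-profile blur (FWHM = slice thickness) along the stack's
slice axis, `D_k` k-space truncation along that axis (blur and
downsampling are combined into a single frequency-domain filter, so
non-integer factors are exact), and `e_k` additive Gaussian noise. The
reconstruction solves

    min_x  sum_k || D_k H_k T_k x - y_k ||_2^2
         + lambda * sum_{s in S} || grad_s x - g_s ||_1

where `S` holds 40 integer shift triples (alpha in [-2,2], beta and gamma
in [0,2], minus the zero triple and negative-sum duplicates),
`grad_s x = x - shift(x, s)` is a circular shift-difference, and the
guidance fields `g_s` are the same differences of the
interpolate-and-average (IAA) image. A subgradient descent with
backtracking line search minimizes the objective from the IAA start;
`lambda = 0.1` by default. Baselines: IAA, an anisotropic TV prior
(`mode = "tv"`), and single-stack SRR (`n = 1`). A quality suite
(3-component Gaussian-mixture fit, partial-volume estimate, SNR, CNR,
PSNR, SSIM) and a fast-spin-echo scan-time calculator round out the
toolbox. See `vignettes/srr-methods.Rmd` for the full account.

## Worked example

```r
library(srrmri)

# ground-truth phantom: 96^3 at 0.5 mm, three tissue classes
ph    <- make_phantom(phantom_spec(geometry_seed = 1))
truth <- ph$image
grid  <- truth$grid

# three orthogonal stacks of 24 x 2 mm slices, small inter-scan motion,
# noise sd 10 (SNR ~ 20)
specs  <- orthogonal_specs(grid, slice_thickness = 2)
center <- grid$origin + (grid$shape - 1) * grid$spacing / 2
tfs    <- simulate_motion(3, 1.5, 1.5, center, seed = 101)
scans  <- simulate_acquisitions(truth, specs, tfs, noise_model(10, 101))

res <- srr_reconstruct(scans, specs, tfs,
                       solver_config(lambda = 0.1, max_iters = 40))
psnr(res$volume, truth)   # 23.96 dB  (the SRR reconstruction)
psnr(res$iaa,    truth)   # 20.88 dB  (the averaging baseline)
```

The ~3 dB gap is the point of the method: averaging improves SNR but
blurs tissue boundaries, while the deconvolution restores through-plane
resolution and suppresses noise at the same time. Sweeping the guidance
weight against the known truth,

```r
lambda_sweep(scans, specs, tfs, truth,
             lambdas = c(0, 0.01, 0.05, 0.1, 0.3, 1),
             config = solver_config(max_iters = 25))
#   lambda  psnr_db      ssim
# 1   0.00 20.24505 0.4662952
# 2   0.01 21.44806 0.5032223
# 3   0.05 23.37443 0.6251363
# 4   0.10 23.95321 0.7710667
# 5   0.30 22.73440 0.7947549
# 6   1.00 20.88480 0.7633710
```

the best weight is strictly positive with a broad optimum around
0.05–0.3: unregularized least squares (`lambda = 0`) amplifies noise in
the deconvolved bands, while too much guidance drags the solution back
to the blurry average.

`run_experiment(run_config())` scripts the whole study (phantom,
simulation, IAA/TV/SISR/SRR, quality reports, comparison table) into an
output directory, and `exec/srrtool` exposes the stages as shell
subcommands (`phantom`, `simulate`, `reconstruct`, `assess`, `plan`,
`experiment`), e.g.

    Rscript exec/srrtool plan --FoV_p 150 --S_p 0.39 --ETL 21 --f_acc 2

prints the scan-time table (120 s per stack at TR 12 s, a 13.1 s maximum
TR at a 120 s budget, the 16.9x data factor, 39.4 min scaled scan time
and 285 matched-SNR averages for direct HR acquisition).

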