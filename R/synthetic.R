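# Synthetic FA phantom: image sequences with known vasculature, dye
# kinetics, regional leakage, inter-frame motion and sensor noise.
#
# The phantom states a world, not a dial: defaults follow the two-phase
# clinical acquisition protocol (20 frames/min for the first 90 s, then
# 5 frames/min to 10 min), an indicator-dilution arterial bolus with slow
# recirculation, veins lagging arteries, tissue tracking a fraction of the
# arterial signal with gradual washout, and Patlak-like dye accumulation
# k * integral(AIF) in leaky regions -- the simplest kinetic model whose
# late phase is linear in normalized units with slope ~ k.

#' Gamma-variate indicator-dilution curve
#'
#' Zero for `t <= t0`, then
#' `amplitude * ((t-t0)/(alpha*beta))^alpha * exp(alpha - (t-t0)/beta)`,
#' peaking with value `amplitude` at `t0 + alpha*beta`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param t0 bolus arrival time (s).
#' @param alpha,beta shape and scale (> 0).
#' @param amplitude peak value (camera units).
#' @return concentration value(s).
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude) {
  stopifnot(alpha > 0, beta > 0)
  x <- t - t0
  out <- numeric(length(t))
  p <- x > 0
  out[p] <- amplitude * (x[p] / (alpha * beta))^alpha * exp(alpha - x[p] / beta)
  out
}

#' Specification of a synthetic FA phantom
#'
#' Defaults encode the acquisition protocol and plausible retinal dye
#' kinetics; see the methods vignette for the rationale behind each value.
#'
#' @param dims frame size (rows, cols), default 128 x 128.
#' @param duration_s total acquisition span (default 600 s).
#' @param phase1_rate,phase1_end_s early-phase frame rate (frames/min,
#'   default 20) and its end (default 90 s).
#' @param phase2_rate late-phase frame rate (frames/min, default 5).
#' @param aif_params gamma-variate bolus parameters `t0`, `alpha`, `beta`,
#'   `amplitude` (defaults: 10 s arrival, peak at 28 s, 150 camera units).
#' @param recirc_frac,recirc_tau_s,systemic_tau_s recirculation plateau:
#'   fraction of the bolus amplitude sustained after first pass (0.35),
#'   its rise time (30 s) and the slow systemic decay (2500 s, matching
#'   fluorescein's plasma half-life of roughly half an hour).
#' @param vein_delay_s venous lag behind the arterial curve (default 3 s).
#' @param tissue_base tissue signal as a fraction of the AIF (default 0.35).
#' @param washout_tau_s extra tissue clearance time constant (350 s);
#'   makes healthy normalized tissue decline in the late phase.
#' @param leak_regions list of `list(mask = <logical matrix>, k = <rate>)`;
#'   `k` is the dye accumulation rate in normalized units per second.
#' @param motion_sd per-frame random-walk translation step (px, default
#'   0.5).
#' @param noise_sd additive Gaussian sensor noise (camera units, default
#'   2).
#' @param baseline,texture_sd sensor pedestal (10 camera units, keeping
#'   the zero-clipping nonlinearity out of play) and smooth fundus texture
#'   amplitude (4 camera units) visible before dye arrival.
#' @param disc_glow,disc_k optic-disc baseline glow (35 camera units) and
#'   its physiological leak rate (1.5e-3 /s).
#' @param eye `"right"` or `"left"`: lateralized disc position.
#' @param seed mandatory integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(128L, 128L), duration_s = 600,
                         phase1_rate = 20, phase1_end_s = 90,
                         phase2_rate = 5,
                         aif_params = list(t0 = 10, alpha = 3, beta = 6,
                                           amplitude = 150),
                         recirc_frac = 0.35, recirc_tau_s = 30,
                         systemic_tau_s = 2500,
                         vein_delay_s = 3, tissue_base = 0.35,
                         washout_tau_s = 350,
                         leak_regions = list(),
                         motion_sd = 0.5, noise_sd = 2,
                         baseline = 10, texture_sd = 4,
                         disc_glow = 35, disc_k = 1.5e-3,
                         eye = "right", seed) {
  if (missing(seed)) stop("phantom seed is mandatory")
  stopifnot(phase1_rate > 0, phase2_rate > 0, phase1_end_s < duration_s)
  for (lr in leak_regions) {
    stopifnot(lr$k >= 0)
    if (!all(dim(lr$mask) == dims))
      stop("leak-region mask dimensions do not match phantom dims")
  }
  eye <- match.arg(eye, c("right", "left"))
  fields <- c("dims", "duration_s", "phase1_rate", "phase1_end_s",
              "phase2_rate", "aif_params", "recirc_frac", "recirc_tau_s",
              "systemic_tau_s", "vein_delay_s", "tissue_base",
              "washout_tau_s", "leak_regions", "motion_sd", "noise_sd",
              "baseline", "texture_sd", "disc_glow", "disc_k", "eye",
              "seed")
  structure(mget(fields), class = "phantom_spec")
}

#' Frame acquisition times of the two-phase protocol
#'
#' Phase 1 covers `[0, phase1_end_s)` at `phase1_rate` frames/min, phase 2
#' covers `[phase1_end_s, duration_s)` at `phase2_rate` frames/min; with
#' the defaults this is 30 + 43 = 73 frames.
#'
#' @param spec a [phantom_spec()].
#' @return numeric vector of seconds since injection.
#' @export
phantom_times <- function(spec) {
  d1 <- 60 / spec$phase1_rate
  t1 <- d1 * (0:ceiling(spec$phase1_end_s / d1))
  t1 <- t1[t1 < spec$phase1_end_s - 1e-9 * spec$phase1_end_s]
  d2 <- 60 / spec$phase2_rate
  t2 <- spec$phase1_end_s +
    d2 * (0:ceiling((spec$duration_s - spec$phase1_end_s) / d2))
  t2 <- t2[t2 < spec$duration_s - 1e-9 * spec$duration_s]
  c(t1, t2)
}

#' Arterial input function of the phantom
#'
#' First-pass gamma-variate bolus plus a slowly decaying recirculation
#' plateau, evaluated at times `t`.
#'
#' @param spec a [phantom_spec()].
#' @param t times in seconds.
#' @return AIF values in camera units.
#' @export
phantom_aif <- function(spec, t) {
  p <- spec$aif_params
  x <- pmax(t - p$t0, 0)
  gamma_variate(t, p$t0, p$alpha, p$beta, p$amplitude) +
    spec$recirc_frac * p$amplitude *
      (1 - exp(-x / spec$recirc_tau_s)) * exp(-x / spec$systemic_tau_s)
}

# cumulative trapezoid of y over t, same length, starting at 0
cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' Circular region mask (leak lesions, optic disc)
#'
#' @param dims (rows, cols).
#' @param center 0-based (row, col) center.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @export
disk_region <- function(dims, center, radius) {
  r <- matrix(0:(dims[1] - 1L), dims[1], dims[2])
  cc <- matrix(0:(dims[2] - 1L), dims[1], dims[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# stamp Gaussian cross-section profiles along a sampled path into `prof`
# (keeping the pointwise maximum); path is n x 2 of 0-based (row, col)
stamp_path <- function(prof, path, width) {
  nr <- nrow(prof); nc <- ncol(prof)
  w <- ceiling(3 * width)
  for (i in seq_len(nrow(path))) {
    r0 <- path[i, 1]; c0 <- path[i, 2]
    rs <- max(0, floor(r0 - w)):min(nr - 1, ceiling(r0 + w))
    cs <- max(0, floor(c0 - w)):min(nc - 1, ceiling(c0 + w))
    if (!length(rs) || !length(cs)) next
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    g <- exp(-d2 / (2 * width^2))
    blk <- prof[rs + 1L, cs + 1L, drop = FALSE]
    prof[rs + 1L, cs + 1L] <- pmax(blk, g)
  }
  prof
}

# parametric vascular arcades leaving the disc: returns list of artery and
# vein intensity profiles in [0,1] (Gaussian cross-sections)
phantom_vessels <- function(dims, disc_center, eye) {
  nr <- dims[1]; nc <- dims[2]
  aprof <- matrix(0, nr, nc); vprof <- matrix(0, nr, nc)
  dir <- if (eye == "right") -1 else 1    # arcades sweep away from the disc
  tt <- seq(0, 1, length.out = 160)
  vside <- 1                              # vein side alternates per branch
  clip_stamp <- function(prof, path, width) {
    okp <- path[, 1] >= 0 & path[, 1] <= nr - 1 &
      path[, 2] >= 0 & path[, 2] <= nc - 1
    stamp_path(prof, path[okp, , drop = FALSE], width)
  }
  for (s in c(-1, 1)) {                   # superior / inferior arcade
    for (bend in c(0.55, 0.8)) {          # two branches per arcade
      rr <- disc_center[1] + s * (0.08 * nr + 0.55 * nr * tt^1.1 * bend)
      cc <- disc_center[2] + dir * (0.9 * nc * tt) -
        dir * 0.25 * nc * bend * tt^2
      path <- cbind(rr, cc)
      aprof <- clip_stamp(aprof, path, width = 1.3)
      # paired vein: parallel, offset a few pixels; side alternates
      # between branches as in real arcades, so transit-phase pseudo-
      # motion from asynchronous artery/vein filling largely cancels
      vside <- -vside
      vpath <- path + matrix(c(vside * s * 3.5, vside * dir * 1.5),
                             nrow(path), 2, byrow = TRUE)
      vprof <- clip_stamp(vprof, vpath, width = 1.6)
      # second-order branches: thinner daughters leaving mid-course at
      # roughly perpendicular headings, as in a real arcade tree
      for (bp in c(0.35, 0.65)) {
        i0 <- which.min(abs(tt - bp))
        u <- seq(0, 0.5, length.out = 80)
        drr <- path[i0, 1] + s * 0.45 * nr * u * (1 - 0.4 * bend)
        dcc <- path[i0, 2] + dir * 0.25 * nc * u - s * 0.05 * nc * u^2
        dpath <- cbind(drr, dcc)
        aprof <- clip_stamp(aprof, dpath, width = 0.9)
        vprof <- clip_stamp(vprof, dpath +
          matrix(c(vside * s * 2.5, -vside * dir * 1.5),
                 nrow(dpath), 2, byrow = TRUE), width = 1.1)
      }
    }
  }
  list(artery = aprof, vein = vprof)
}

# smooth random background texture (static across frames): a coarse
# choroidal-scale field plus a finer nerve-fiber-scale component, both
# band-limited so the Fourier motion model is exact for them
phantom_texture <- function(dims, sd) {
  smooth_field <- function(sigma) {
    z <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    z <- blur_gauss(z, sigma)
    z / stats::sd(z)
  }
  (0.6 * smooth_field(4) + 0.8 * smooth_field(1.8)) * sd
}

# pixel-coverage profile of the optic disc at a given (possibly shifted)
# center: 1 inside, 0 outside, linear 1-px ramp at the rim (the sensor's
# areal integration of a sharp anatomical edge)
disc_profile <- function(dims, center, radius) {
  rg <- matrix(0:(dims[1] - 1L), dims[1], dims[2])
  cg <- matrix(0:(dims[2] - 1L), dims[1], dims[2], byrow = TRUE)
  d <- sqrt((rg - center[1])^2 + (cg - center[2])^2)
  pmin(pmax(radius + 0.5 - d, 0), 1)
}

#' Generate a synthetic FA sequence with known ground truth
#'
#' Per-pixel intensity combines: arteries tracing the AIF, veins tracing
#' it delayed by `vein_delay_s`, tissue following
#' `tissue_base * AIF(t) * exp(-(t - t0)/washout_tau_s) + k * integral(AIF)`
#' (so zero-k tissue washes out and leaky tissue accumulates linearly in
#' normalized units), a bright lateralized optic-disc blob with
#' physiological leak, a static smooth background texture, a per-frame
#' random-walk translation (recorded in the truth), and additive Gaussian
#' sensor noise clipped at zero.  Identical seeds give identical output.
#'
#' Motion is realized by translating the band-limited scene (vessels,
#' tissue, texture) with an exact Fourier shift, while the sharp-edged
#' disc is re-rendered analytically at its translated position with a
#' pixel-coverage rim -- so no frame carries resampling (aliasing)
#' artifacts of the sharp edge.  Sensor noise is drawn after the motion.
#'
#' @param spec a [phantom_spec()].
#' @return list with `sequence` (an [fa_sequence()]) and `truth` (list:
#'   `leak_map`, `true_shifts`, `artery_mask`, `vein_mask` (vessel cores,
#'   profile > 0.6), `vessel_cov` (continuous vascular coverage in
#'   \code{[0, 1]}; pixels with `vessel_cov < 0.05` are pure tissue),
#'   `disc_mask`, `artery_prof`/`vein_prof` (continuous profiles, see
#'   [phantom_masks_at()]), `disc_center`, `disc_radius`, `aif`, `times`).
#'   All truth rasters live in the canonical (zero-shift) frame; use
#'   [phantom_masks_at()] to obtain them in a registered stack's
#'   coordinates.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  dims <- as.integer(spec$dims)
  nr <- dims[1]; nc <- dims[2]
  times <- phantom_times(spec)
  nt <- length(times)
  disc_center <- c(0.5 * (nr - 1),
                   if (spec$eye == "right") 0.75 * (nc - 1) else 0.25 * (nc - 1))
  disc_r <- 0.07 * min(dims)
  rg <- matrix(0:(nr - 1L), nr, nc)
  cg <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  disc_dist <- sqrt((rg - disc_center[1])^2 + (cg - disc_center[2])^2)
  disc <- disc_dist <= disc_r + 4      # truth mask, dilated past the rim
  ves <- phantom_vessels(dims, disc_center, spec$eye)
  texture <- phantom_texture(dims, spec$texture_sd)

  # lesion leak map; edges softened by ~1 px so the growing lesions stay
  # band-limited under the Fourier motion model
  leak <- matrix(0, nr, nc)
  for (lr in spec$leak_regions) leak[lr$mask] <- lr$k
  if (length(spec$leak_regions)) leak <- blur_gauss(leak, 1)
  leak_disc <- spec$disc_k

  aif <- phantom_aif(spec, times)
  aif_d <- phantom_aif(spec, times - spec$vein_delay_s)
  cumaif <- cumtrapz(times, aif)
  wash <- exp(-pmax(times - spec$aif_params$t0, 0) / spec$washout_tau_s)

  vessel_cov <- pmin(ves$artery + ves$vein, 1)
  shifts <- matrix(0, nt, 2)
  if (spec$motion_sd > 0 && nt > 1)
    shifts[-1, ] <- apply(matrix(stats::rnorm(2 * (nt - 1),
                                              sd = spec$motion_sd),
                                 ncol = 2), 2, cumsum)
  frames <- vector("list", nt)
  for (j in seq_len(nt)) {
    tis <- spec$tissue_base * aif[j] * wash[j] + leak * cumaif[j]
    scene <- spec$baseline + texture +
      ves$artery * aif[j] + ves$vein * aif_d[j] +
      (1 - vessel_cov) * tis
    if (any(shifts[j, ] != 0)) scene <- apply_shift(scene, -shifts[j, ])
    dp <- blur_gauss(disc_profile(dims, disc_center + shifts[j, ], disc_r),
                     0.7)
    img <- (1 - dp) * scene +
      dp * (spec$baseline + spec$disc_glow + 1.2 * aif[j] +
            leak_disc * cumaif[j])
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, sd = spec$noise_sd)
    frames[[j]] <- fa_frame(pmax(img, 0), t = times[j], eye = spec$eye)
  }
  leak_truth <- leak
  leak_truth[disc_dist <= disc_r] <- leak_disc
  truth <- list(
    leak_map = leak_truth,
    true_shifts = lapply(seq_len(nt), function(j)
      shift_vector(shifts[j, 1], shifts[j, 2])),
    artery_prof = ves$artery, vein_prof = ves$vein,
    artery_mask = roi_mask(ves$artery > 0.6 & !disc, "artery"),
    vein_mask = roi_mask(ves$vein > 0.6 & !disc, "other"),
    vessel_cov = vessel_cov,
    disc_mask = roi_mask(disc, "optic_disc"),
    disc_center = disc_center, disc_radius = disc_r,
    aif = aif, times = times)
  list(sequence = fa_sequence(frames), truth = truth)
}

# Gaussian blur via separable filtering with reflect padding
blur_gauss <- function(x, sigma) {
  k <- stats::dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma)
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  x <- apply(x, 2, function(v) stats::filter(c(rev(v), v, rev(v)), k,
                                             sides = 2)[(n + 1):(2 * n)])
  t(apply(x, 1, function(v) stats::filter(c(rev(v), v, rev(v)), k,
                                          sides = 2)[(m + 1):(2 * m)]))
}

#' Phantom truth masks in a translated coordinate frame
#'
#' A registered stack lives in the coordinates of its reference frame,
#' which itself sits at some drift relative to the phantom's canonical
#' frame.  This helper re-renders the truth masks at that drift so they
#' overlay the registered images exactly: continuous vessel profiles are
#' Fourier-shifted (they are band-limited), the disc analytically.
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @param shift numeric `(d_row, d_col)` or [shift_vector()]: the drift of
#'   the target frame (e.g. the true shift of the reference frame).
#' @return list with `artery_mask`, `vein_mask`, `disc_mask` (roi_mask),
#'   and `vessel_cov` (numeric matrix).
#' @export
phantom_masks_at <- function(truth, shift) {
  if (inherits(shift, "shift_vector")) shift <- c(shift$d_row, shift$d_col)
  dims <- dim(truth$vessel_cov)
  ap <- apply_shift(truth$artery_prof, -shift)
  vp <- apply_shift(truth$vein_prof, -shift)
  cov <- pmin(pmax(ap, 0) + pmax(vp, 0), 1)
  disc <- disk_region(dims, truth$disc_center + shift,
                      truth$disc_radius + 4)
  list(artery_mask = roi_mask(ap > 0.6 & !disc, "artery"),
       vein_mask = roi_mask(vp > 0.6 & !disc, "other"),
       disc_mask = roi_mask(disc, "optic_disc"),
       vessel_cov = cov)
}

#' Generate a synthetic cohort of healthy and patient phantoms
#'
#' Healthy subjects have no leak outside the optic disc; patients carry
#' 1--4 circular leak regions with rates drawn log-uniformly from
#' `k_range`.  Per-subject seeds derive deterministically from the master
#' seed, so the same master seed reproduces the identical cohort.
#'
#' @param base_spec a [phantom_spec()] used as the template (its own
#'   `leak_regions` and `seed` are overridden).
#' @param n_healthy,n_patient cohort sizes (defaults 8 and 13, the typical
#'   small pilot design).
#' @param seed master integer seed.
#' @param k_range log-uniform range of patient leak rates (normalized
#'   units/s), default `c(3e-4, 3e-3)`.
#' @param lesion_radius_px range of lesion radii in pixels, default
#'   `c(8, 20)` at 128 px frame size.
#' @return list of `list(sequence, truth, group)` with `group` in
#'   `{"healthy", "patient"}`.
#' @export
generate_cohort <- function(base_spec, n_healthy = 8L, n_patient = 13L,
                            seed, k_range = c(3e-4, 3e-3),
                            lesion_radius_px = c(8, 20)) {
  if (missing(seed)) stop("a master seed is required")
  stopifnot(n_healthy >= 0, n_patient >= 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- n_healthy + n_patient
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  dims <- as.integer(base_spec$dims)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    patient <- i > n_healthy
    spec <- base_spec
    spec$seed <- sub_seeds[i]
    spec$eye <- sample(c("right", "left"), 1)
    spec$leak_regions <- list()
    if (patient) {
      n_reg <- sample(1:4, 1)
      for (j in seq_len(n_reg)) {
        rad <- stats::runif(1, lesion_radius_px[1], lesion_radius_px[2]) *
          min(dims) / 128
        center <- c(stats::runif(1, rad, dims[1] - 1 - rad),
                    stats::runif(1, rad, dims[2] - 1 - rad))
        k <- exp(stats::runif(1, log(k_range[1]), log(k_range[2])))
        spec$leak_regions <- c(spec$leak_regions,
                               list(list(mask = disk_region(dims, center, rad),
                                         k = k)))
      }
    }
    out[[i]] <- c(generate_phantom(spec),
                  list(group = if (patient) "patient" else "healthy"))
  }
  out
}
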