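#' Registration configuration
#'
#' Collects the tunable parameters of [register()]. Defaults follow common
#' practice for multi-resolution mutual-information registration of CT
#' volumes: 32 histogram bins, 4096 random in-mask samples, a three-level
#' Gaussian pyramid (shrink 4/2/1, smoothing 2/1/0 voxels), at most 250
#' gradient-ascent iterations per level with an adaptive step halved on
#' metric worsening, and convergence when the metric changes by less than
#' `tol` (relative) over `patience` iterations. All randomness is governed
#' by `seed`; a fixed seed makes runs bit-reproducible.
#'
#' @param stages character vector of transform kinds to optimise in order,
#'   from `"translation"`, `"rigid"`, `"affine"`, `"bspline"`. Each later
#'   stage is composed with (initialised from) the previous stages' result.
#' @param bins MI histogram bins per image.
#' @param samples random samples drawn from the fixed mask per level
#'   (`Inf` = all) for the low-dimensional stages.
#' @param bspline_samples samples for the B-spline stage; its thousands of
#'   coefficients need a much larger sample than the handful of rigid or
#'   affine parameters, otherwise the warp fits joint-histogram noise.
#' @param shrink integer shrink factor per pyramid level (coarse to fine).
#' @param smooth Gaussian smoothing sigma (voxels) per level.
#' @param max_iterations iteration cap per level.
#' @param cp_spacing isotropic B-spline control-point spacing (mm).
#' @param tol relative metric-change convergence tolerance.
#' @param patience iterations over which `tol` is assessed.
#' @param step_initial initial ascent step (mm) per level; default
#'   `pmax(shrink, 1)`.
#' @param min_step smallest ascent step (mm) before a level stops.
#' @param fd_step central finite-difference step (in characteristic
#'   parameter units, roughly mm) for the gradients of low-dimensional
#'   stages.
#' @param bspline_optimizer optimiser for the B-spline stage:
#'   `"lbfgs"` (limited-memory quasi-Newton on the analytic gradient,
#'   default) or `"ascent"` (the same adaptive-step gradient ascent used
#'   for the low-dimensional stages).
#' @param bspline_regularization weight of the membrane (first-difference)
#'   smoothness penalty on the B-spline coefficient lattice, subtracted
#'   from the metric; discourages histogram-noise-driven warps that a
#'   finite sample cannot constrain.
#' @param clamp intensity clamp (HU) applied before histogramming.
#' @param seed RNG seed for sampling.
#' @param initial_chain a [transform_chain] applied before all optimised
#'   stages (e.g. a recorded couch shift); not optimised.
#' @param verbose print per-level progress.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(stages = c("affine", "bspline"),
                                bins = 32,
                                samples = 4096,
                                bspline_samples = 32768,
                                shrink = c(4, 2, 1),
                                smooth = c(2, 1, 0),
                                max_iterations = 250,
                                cp_spacing = 15,
                                tol = 1e-5,
                                patience = 10,
                                step_initial = NULL,
                                min_step = 0.01,
                                fd_step = 0.25,
                                bspline_optimizer = c("lbfgs", "ascent"),
                                bspline_regularization = 0.15,
                                clamp = c(-1024, 3071),
                                seed = 1,
                                initial_chain = NULL,
                                verbose = FALSE) {
  stages <- match.arg(stages, c("translation", "rigid", "affine", "bspline"),
                      several.ok = TRUE)
  bspline_optimizer <- match.arg(bspline_optimizer)
  if (length(shrink) != length(smooth))
    stop("'shrink' and 'smooth' must have the same length")
  if (any(c(bins, samples, max_iterations, cp_spacing, patience) <= 0))
    stop("counts and spacings must be positive")
  if (is.null(step_initial)) step_initial <- pmax(shrink, 1)
  structure(list(stages = stages, bins = bins, samples = samples,
                 bspline_samples = bspline_samples,
                 shrink = shrink, smooth = smooth,
                 max_iterations = max_iterations, cp_spacing = cp_spacing,
                 tol = tol, patience = patience, step_initial = step_initial,
                 min_step = min_step, fd_step = fd_step,
                 bspline_optimizer = bspline_optimizer,
                 bspline_regularization = bspline_regularization,
                 clamp = clamp, seed = seed,
                 initial_chain = initial_chain, verbose = verbose),
            class = "registration_config")
}

# Gaussian-smoothed, subsampled pyramid level of a volume.
pyramid_level <- function(volume, shrink, smooth_sigma) {
  d <- dim(volume$voxels)
  f <- pmax(1L, pmin(as.integer(shrink), d %/% 4L))
  vox <- as.numeric(volume$voxels)
  sig <- rep(smooth_sigma, length.out = 3) * (f > 1)
  if (any(sig > 0)) vox <- cpp_smooth3(vox, d, sig)
  arr <- array(vox, dim = d)
  arr <- arr[seq(1, d[1], by = f[1]), seq(1, d[2], by = f[2]),
             seq(1, d[3], by = f[3]), drop = FALSE]
  image_volume(arr, spacing = volume$spacing * f, origin = volume$origin)
}

# Limited-memory BFGS ascent of the metric using the analytic gradient
# (maximisation via negation). Used for the high-dimensional B-spline stage
# where plain steepest ascent converges too slowly.
opt_lbfgs <- function(par, fn, gr, max_iter, tol) {
  f0 <- fn(par)
  if (!is.finite(f0))
    stop("insufficient overlap or non-finite metric at the initial parameters")
  res <- stats::optim(par, fn = function(p) -fn(p), gr = function(p) -gr(p),
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = tol / 1e-15))
  list(par = res$par, value = -res$value, trajectory = c(f0, -res$value),
       iterations = res$counts[["function"]],
       stalled = res$convergence != 0 && res$convergence != 1)
}

# Adaptive-step gradient ascent with parameter scaling. `scales` gives the
# per-parameter characteristic unit (mm of displacement per unit parameter
# change is roughly 1/scales); steps are taken along scales^2 * gradient,
# normalised so `step` is approximately in mm.
opt_ascent <- function(par, fn, gr, scales, step0, max_iter, tol, patience,
                       min_step, norm = c("l2", "linf")) {
  norm <- match.arg(norm)
  f <- fn(par)
  if (!is.finite(f))
    stop("insufficient overlap or non-finite metric at the initial parameters")
  traj <- f
  step <- step0
  stalled <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gr(par)
    gs_norm <- if (norm == "l2") sqrt(sum((g * scales)^2))
               else max(abs(g * scales))
    if (!is.finite(gs_norm) || gs_norm < 1e-14) break
    dir <- (scales^2 * g) / gs_norm
    accepted <- FALSE
    while (step >= min_step) {
      cand <- par + step * dir
      fc <- fn(cand)
      if (is.finite(fc) && fc > f + 1e-14) {
        par <- cand
        f <- fc
        accepted <- TRUE
        step <- min(step * 1.2, step0 * 4)
        break
      }
      step <- step / 2
    }
    traj <- c(traj, f)
    if (!accepted) {
      stalled <- TRUE
      break
    }
    if (length(traj) > patience) {
      recent <- traj[(length(traj) - patience):length(traj)]
      if (max(recent) - min(recent) < tol * max(abs(f), 1e-8)) break
    }
  }
  list(par = par, value = f, trajectory = traj,
       iterations = length(traj) - 1, stalled = stalled)
}

stage_template <- function(kind, center) {
  switch(kind,
         translation = list(par = numeric(3), scales = rep(1, 3)),
         rigid = {
           r_eff <- 100
           list(par = numeric(6),
                scales = c(rep(1 / r_eff, 3), rep(1, 3)))
         },
         affine = {
           r_eff <- 100
           list(par = c(as.numeric(diag(3)), 0, 0, 0),
                scales = c(rep(1 / r_eff, 9), rep(1, 3)))
         },
         stop("unknown stage kind ", kind))
}

stage_from_par <- function(kind, par, center) {
  switch(kind,
         translation = translation_transform(par),
         rigid = rigid_transform(par[1:3], par[4:6], center),
         affine = affine_transform(matrix(par[1:9], 3, 3), par[10:12], center))
}

#' Register a moving volume to a fixed volume
#'
#' Estimates a [transform_chain] mapping fixed-frame points to moving-frame
#' points by maximising mutual information between the fixed image (sampled
#' inside the body mask) and the transformed moving image. Stages listed in
#' `config$stages` are optimised in order, each initialised from (composed
#' after) the previous stages' result, over a coarse-to-fine Gaussian
#' pyramid. Low-dimensional stages use finite-difference gradients of the
#' Parzen-smoothed metric; the B-spline stage uses analytic gradients with
#' respect to its control-point coefficients.
#'
#' @param fixed the fixed [image_volume] (planning kVCT frame).
#' @param moving the moving [image_volume] (guidance MVCT frame).
#' @param mask optional `binary_mask` on the fixed grid; when `NULL`, a
#'   body mask is built with [build_body_mask()].
#' @param config a [registration_config].
#' @return A [transform_chain] (including any `initial_chain` stages) with
#'   attributes `log` (per-stage, per-level metric trajectories), `mask`
#'   and `config`. A stage that stalls before convergence is flagged in the
#'   log and via a warning.
#' @export
register <- function(fixed, moving, mask = NULL,
                     config = registration_config()) {
  stopifnot_volume(fixed)
  stopifnot_volume(moving)
  if (is.null(mask)) mask <- build_body_mask(fixed)
  if (!is_binary_mask(mask)) stop("mask must be a binary_mask")
  if (!all(dim(mask$voxels) == dim(fixed$voxels)))
    stop("mask geometry must match the fixed volume")

  d <- dim(fixed$voxels)
  center <- fixed$origin + (d - 1) * fixed$spacing / 2
  chain <- if (is.null(config$initial_chain)) transform_chain()
           else as_chain(config$initial_chain)
  nlev <- length(config$shrink)
  log <- list()

  for (stage_kind in config$stages) {
    bspline_stage <- NULL
    tmpl <- if (stage_kind == "bspline") NULL else stage_template(stage_kind, center)
    par <- tmpl$par
    stage_log <- list()

    for (lev in seq_len(nlev)) {
      f_lev <- pyramid_level(fixed, config$shrink[lev], config$smooth[lev])
      m_lev <- pyramid_level(moving, config$shrink[lev], config$smooth[lev])
      fmask <- pmax(1L, pmin(as.integer(config$shrink[lev]), d %/% 4L))
      mask_lev <- mask$voxels[seq(1, d[1], by = fmask[1]),
                              seq(1, d[2], by = fmask[2]),
                              seq(1, d[3], by = fmask[3]), drop = FALSE]
      idx <- which(mask_lev)
      if (length(idx) == 0) stop("mask is empty at pyramid level ", lev)
      n_samp <- if (stage_kind == "bspline") config$bspline_samples
                else config$samples
      if (is.finite(n_samp) && n_samp < length(idx)) {
        seed_lev <- config$seed + 1000L * lev +
          match(stage_kind, c("translation", "rigid", "affine", "bspline"))
        idx <- with_seed(seed_lev, sample(idx, n_samp))
      }
      dl <- dim(f_lev$voxels)
      i0 <- (idx - 1L) %% dl[1]
      j0 <- ((idx - 1L) %/% dl[1]) %% dl[2]
      k0 <- (idx - 1L) %/% (dl[1] * dl[2])
      pts <- cbind(f_lev$origin[1] + i0 * f_lev$spacing[1],
                   f_lev$origin[2] + j0 * f_lev$spacing[2],
                   f_lev$origin[3] + k0 * f_lev$spacing[3])
      fvals <- clamp_hu(f_lev$voxels[idx], config$clamp)
      fsetup <- mi_bin_setup(clamp_hu(as.numeric(f_lev$voxels), config$clamp),
                             config$bins)
      fbin <- mi_bin_index(fvals, fsetup, config$bins)
      mvals <- clamp_hu(as.numeric(m_lev$voxels), config$clamp)
      msetup <- mi_bin_setup(mvals, config$bins)
      mdim <- dim(m_lev$voxels)

      y <- transform_point(chain, pts)

      if (stage_kind == "bspline") {
        if (is.null(bspline_stage)) {
          lo <- apply(y, 2, min)
          hi <- apply(y, 2, max)
          grid <- bspline_grid_covering(lo, hi, config$cp_spacing)
          bspline_stage <- bspline_transform(grid$origin, grid$spacing,
                                             grid$dim)
          par <- bspline_stage$params
        }
        gd <- bspline_stage$grid_dim
        lambda <- config$bspline_regularization
        # bending-energy style penalty: mean squared second difference of
        # the coefficient lattice along each axis. Zero for constant and
        # linearly varying (affine-like) fields, so smooth anatomical warps
        # are not shrunk; high-curvature histogram-noise warps are.
        nterms <- 3 * ((gd[1] - 2) * gd[2] * gd[3] +
                       gd[1] * (gd[2] - 2) * gd[3] +
                       gd[1] * gd[2] * (gd[3] - 2))
        second_diffs <- function(C) {
          g1 <- gd[1]; g2 <- gd[2]; g3 <- gd[3]
          list(
            x = C[-c(1, 2), , , , drop = FALSE] -
              2 * C[-c(1, g1), , , , drop = FALSE] +
              C[-c(g1 - 1, g1), , , , drop = FALSE],
            y = C[, -c(1, 2), , , drop = FALSE] -
              2 * C[, -c(1, g2), , , drop = FALSE] +
              C[, -c(g2 - 1, g2), , , drop = FALSE],
            z = C[, , -c(1, 2), , drop = FALSE] -
              2 * C[, , -c(1, g3), , drop = FALSE] +
              C[, , -c(g3 - 1, g3), , drop = FALSE])
        }
        penalty <- function(p) {
          d2 <- second_diffs(array(p, dim = c(gd, 3)))
          (sum(d2$x^2) + sum(d2$y^2) + sum(d2$z^2)) / nterms
        }
        penalty_grad <- function(p) {
          d2 <- second_diffs(array(p, dim = c(gd, 3)))
          G <- array(0, dim = c(gd, 3))
          g1 <- gd[1]; g2 <- gd[2]; g3 <- gd[3]
          G[-c(1, 2), , , ] <- G[-c(1, 2), , , , drop = FALSE] + 2 * d2$x
          G[-c(1, g1), , , ] <- G[-c(1, g1), , , , drop = FALSE] - 4 * d2$x
          G[-c(g1 - 1, g1), , , ] <-
            G[-c(g1 - 1, g1), , , , drop = FALSE] + 2 * d2$x
          G[, -c(1, 2), , ] <- G[, -c(1, 2), , , drop = FALSE] + 2 * d2$y
          G[, -c(1, g2), , ] <- G[, -c(1, g2), , , drop = FALSE] - 4 * d2$y
          G[, -c(g2 - 1, g2), , ] <-
            G[, -c(g2 - 1, g2), , , drop = FALSE] + 2 * d2$y
          G[, , -c(1, 2), ] <- G[, , -c(1, 2), , drop = FALSE] + 2 * d2$z
          G[, , -c(1, g3), ] <- G[, , -c(1, g3), , drop = FALSE] - 4 * d2$z
          G[, , -c(g3 - 1, g3), ] <-
            G[, , -c(g3 - 1, g3), , drop = FALSE] + 2 * d2$z
          as.numeric(G) / nterms
        }
        cache <- new.env(parent = emptyenv())
        eval_bspline <- function(p) {
          if (!is.null(cache$par) && identical(cache$par, p)) return(cache$res)
          st <- bspline_stage
          st$params <- p
          res <- cpp_bspline_mi_grad(y, fbin, st, mvals, mdim, m_lev$spacing,
                                     m_lev$origin, msetup$min, msetup$width,
                                     config$bins, config$bins)
          cache$par <- p
          cache$res <- res
          res
        }
        fn <- function(p) {
          r <- eval_bspline(p)
          if (r$n_used < 0.1 * r$n_attempted) return(-Inf)
          r$mi - lambda * penalty(p)
        }
        gr <- function(p) eval_bspline(p)$grad - lambda * penalty_grad(p)
        scales <- rep(1, length(par))
      } else {
        fn <- function(p) {
          st <- stage_from_par(stage_kind, p, center)
          r <- cpp_chain_mi(y, fbin, list(st), mvals, mdim, m_lev$spacing,
                            m_lev$origin, msetup$min, msetup$width,
                            config$bins, config$bins, TRUE)
          if (r$n_used < 0.1 * r$n_attempted) return(-Inf)
          r$mi
        }
        scales <- tmpl$scales
        eps <- config$fd_step * scales
        gr <- function(p) {
          vapply(seq_along(p), function(i) {
            up <- p; up[i] <- up[i] + eps[i]
            dn <- p; dn[i] <- dn[i] - eps[i]
            (fn(up) - fn(dn)) / (2 * eps[i])
          }, 0)
        }
      }

      res <- if (stage_kind == "bspline" &&
                 config$bspline_optimizer == "lbfgs") {
        opt_lbfgs(par, fn, gr, max_iter = config$max_iterations,
                  tol = config$tol)
      } else {
        opt_ascent(par, fn, gr, scales,
                   step0 = config$step_initial[min(lev, length(config$step_initial))],
                   max_iter = config$max_iterations,
                   tol = config$tol, patience = config$patience,
                   min_step = config$min_step,
                   norm = if (stage_kind == "bspline") "linf" else "l2")
      }
      par <- res$par
      stage_log[[lev]] <- list(level = lev, iterations = res$iterations,
                               mi_initial = res$trajectory[1],
                               mi_final = res$value,
                               trajectory = res$trajectory,
                               stalled = res$stalled)
      if (config$verbose)
        message(sprintf("stage %s level %d: MI %.5f -> %.5f (%d iterations)",
                        stage_kind, lev, res$trajectory[1], res$value,
                        res$iterations))
    }

    final_stage <- if (stage_kind == "bspline") {
      st <- bspline_stage
      st$params <- par
      st
    } else stage_from_par(stage_kind, par, center)
    chain <- transform_chain(c(unclass(chain), list(final_stage)))
    log[[stage_kind]] <- stage_log
  }

  attr(chain, "log") <- log
  attr(chain, "config") <- config
  stalled_any <- any(vapply(log, function(sl)
    any(vapply(sl, `[[`, TRUE, "stalled")), TRUE))
  attr(chain, "stalled") <- stalled_any
  chain
}
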