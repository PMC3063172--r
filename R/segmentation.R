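#' Pipeline configuration
#'
#' Collects every tunable constant of the detection pipeline in one
#' serialisable object: the 1.5 mm isotropic working resolution; the number
#' of Gaussians per tissue class (3, 2, 2, 3, 2, 4 for GWM, CSF, CMB,
#' "skull", "scalp", "other"); the flat in-brain CMB prior (0.1); the
#' first-pass binarisation threshold (0.2); the size bounds (at least 2
#' contiguous voxels, at most 0.675 cm^3 — a cylinder two slices high by
#' 8 mm diameter separating microbleeds from macrobleeds); the skull and CSF
#' masking thresholds (0.5); the final second-pass probability threshold
#' (0.5); and the EM controls.
#'
#' @param working_spacing isotropic working resolution, mm.
#' @param n_gaussians named integer vector of Gaussians per class.
#' @param cmb_prior_value flat in-brain CMB prior.
#' @param binarise_threshold first-pass binarisation threshold (inclusive).
#' @param min_voxels minimum component size in voxels (inclusive bound;
#'   smaller components are discarded).
#' @param max_volume_cm3 maximum component volume (strict bound; larger
#'   components are discarded as macrobleed-sized).
#' @param skull_threshold skull-posterior masking threshold (inclusive).
#' @param csf_threshold CSF-posterior exclusion threshold (strict).
#' @param final_threshold second-pass probability threshold.
#' @param em_tol relative log-likelihood convergence tolerance.
#' @param em_max_iter maximum EM iterations.
#' @param bias_degree polynomial degree of the bias-field basis (0 disables
#'   bias correction).
#' @param bias_interval EM iterations between bias-field updates.
#' @param connectivity component connectivity (26: diagonal-touching
#'   hypointensities on thick slices count as one lesion).
#' @param neighbour_connectivity dilation connectivity for the CSF
#'   nearest-neighbour exclusion (6, conservative).
#' @param constraint_eps relative clipping margin of the mean constraints.
#' @param variance_floor_frac variance floor as a fraction of the in-brain
#'   intensity range (floor = (frac * range)^2).
#' @param seed integer seed recorded with every run.
#' @return A list of class `midas_config`.
#' @export
midas_config <- function(working_spacing = 1.5,
                         n_gaussians = c(GWM = 3L, CSF = 2L, CMB = 2L,
                                         skull = 3L, scalp = 2L, other = 4L),
                         cmb_prior_value = 0.1,
                         binarise_threshold = 0.2,
                         min_voxels = 2L,
                         max_volume_cm3 = 0.675,
                         skull_threshold = 0.5,
                         csf_threshold = 0.5,
                         final_threshold = 0.5,
                         em_tol = 1e-5,
                         em_max_iter = 100L,
                         bias_degree = 3L,
                         bias_interval = 3L,
                         connectivity = 26L,
                         neighbour_connectivity = 6L,
                         constraint_eps = 1e-3,
                         variance_floor_frac = 0.01,
                         seed = 1L) {
  stopifnot(working_spacing > 0,
            binarise_threshold >= 0, binarise_threshold <= 1,
            final_threshold >= 0, final_threshold <= 1,
            skull_threshold >= 0, skull_threshold <= 1,
            csf_threshold >= 0, csf_threshold <= 1,
            min_voxels >= 1, max_volume_cm3 > 0,
            connectivity %in% c(6L, 26L),
            neighbour_connectivity %in% c(6L, 26L),
            em_tol > 0, em_max_iter >= 1)
  structure(as.list(environment()), class = "midas_config")
}

# weighted least squares with MAD-based outlier trimming: partial-volume
# voxels at tissue boundaries leave large structured log-residuals that
# would otherwise bend the bias polynomial
robust_wls <- function(X, t, w, rounds = 2L) {
  fit1 <- function(rows) {
    cf <- stats::lm.wfit(X[rows, , drop = FALSE], t[rows], w[rows])$coef
    cf[!is.finite(cf)] <- 0  # aliased columns (degenerate geometry)
    cf
  }
  keep <- w > 0
  cf <- fit1(keep)
  for (r in seq_len(rounds)) {
    res <- t - as.vector(X %*% cf)
    s <- stats::mad(res[keep])
    if (!is.finite(s) || s <= 0) break
    keep <- w > 0 & abs(res) < 3 * s
    cf <- fit1(keep)
  }
  cf
}

# weighted quantile (type-7-ish on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

init_mixture <- function(y, P, classes, n_gaussians, brain, varfloor) {
  rng <- range(y)
  comps <- list()
  for (k in seq_along(classes)) {
    nk <- n_gaussians[[classes[k]]]
    if (classes[k] == "CMB") {
      # microbleeds are the darkest in-brain tissue: seed at the extreme
      # low quantiles of the in-brain intensity distribution
      probs <- if (nk == 2) c(0.02, 0.10) else
        seq(0.02, 0.10, length.out = nk)
      mu <- stats::quantile(y[brain], probs, names = FALSE)
    } else {
      probs <- (seq_len(nk) - 0.5) / nk
      w <- P[, k]
      mu <- if (sum(w) > 0) weighted_quantile(y, w, probs) else
        stats::quantile(y, probs, names = FALSE)
    }
    comps[[k]] <- data.frame(class = classes[k], w = rep(1 / nk, nk),
                             mu = mu,
                             s2 = rep(max((diff(rng) / 10)^2, varfloor), nk))
  }
  do.call(rbind, comps)
}

#' Project class means onto the intensity-ordering constraints
#'
#' Enforces the two empirical constraints of the model by clipping after
#' each M-step: (i) every CSF Gaussian mean must exceed the
#' posterior-weighted GWM mean (CSF is the brightest brain tissue on T2*);
#' (ii) every microbleed Gaussian mean must stay below 50% of the GWM mean
#' (the search for microbleeds is confined to the dark half of the
#' histogram). Clipping lands just inside the bound, at a relative margin
#' `eps`.
#'
#' @param model a `mixture_model` (the `gwm_mean` field must be current).
#' @param eps relative clipping margin (default 1e-3).
#' @return The model with clipped means; attribute `clipped` says whether
#'   any mean moved.
#' @export
constrain_means <- function(model, eps = 1e-3) {
  stopifnot(inherits(model, "mixture_model"))
  g <- model$gwm_mean
  comps <- model$comps
  clipped <- FALSE
  csf <- comps$class == "CSF"
  low <- csf & comps$mu <= g
  if (any(low)) { comps$mu[low] <- g * (1 + eps); clipped <- TRUE }
  cmb <- comps$class == "CMB"
  high <- cmb & comps$mu >= 0.5 * g
  if (any(high)) { comps$mu[high] <- 0.5 * g * (1 - eps); clipped <- TRUE }
  model$comps <- comps
  attr(model, "clipped") <- clipped
  model
}

posterior_weighted_gwm_mean <- function(comps) {
  g <- comps$class == "GWM"
  sum(comps$N[g] * comps$mu[g]) / sum(comps$N[g])
}

#' Fit the constrained Gaussian mixture with spatial priors
#'
#' Expectation-Maximisation fit of the six-class mixture to a T2* volume:
#' the E-step computes responsibilities proportional to
#' `prior_k(x) * w_kj * N(y(x)/bias(x); mu_kj, s2_kj)`; the M-step updates
#' means, variances and within-class weights; the class-mean constraints are
#' enforced by projection ([constrain_means()]); and the multiplicative
#' bias field is re-estimated every `bias_interval` iterations by weighted
#' least squares on the log-residuals. Voxels where a class prior is
#' exactly zero keep exactly zero posterior for that class.
#'
#' The EM runs over the head support (voxels where the background prior is
#' below 1); far background keeps its prior as posterior.
#'
#' @param vol a [volume3d].
#' @param priors a `tissue_prior_set` on the same grid.
#' @param config a [midas_config()].
#' @param init_model optional `mixture_model` used as a warm start (e.g. the
#'   first-pass fit when re-segmenting with refined priors).
#' @param reinit_classes classes re-initialised from the data even when
#'   `init_model` is given. The pipeline re-initialises the CMB class in
#'   the second pass: its prior support has changed and the first-pass
#'   Gaussians, clipped against the mean ceiling, may carry a collapsed
#'   variance that would starve the class.
#' @param constrained_variance when `TRUE`, component variances are the
#'   second moment about the projected (clipped) means — the constrained
#'   maximum-likelihood update. The default (`FALSE`) uses the standard
#'   M-step about the raw means before clipping, which keeps the CMB
#'   class tightly focused on dark voxels; the pipeline enables the
#'   constrained update only in the second pass.
#' @return List of class `midas_fit` with `model` (a `mixture_model`:
#'   component table, `gwm_mean`, log-likelihood `trace`, convergence
#'   flags), `posteriors` (named list of six [volume3d] probability maps)
#'   and `bias` (a `bias_field`: coefficients plus realised field).
#' @export
fit_constrained_mixture <- function(vol, priors, config = midas_config(),
                                    init_model = NULL,
                                    reinit_classes = character(0),
                                    constrained_variance = FALSE) {
  stopifnot(inherits(vol, "volume3d"), inherits(priors, "tissue_prior_set"))
  if (!same_grid(vol, priors$maps[[1]]))
    stop("volume and priors are not on the same grid")
  classes <- names(priors$maps)
  P <- prior_matrix(priors)

  active <- if ("other" %in% classes)
    which(P[, "other"] < 1 - 1e-9) else seq_len(nrow(P))
  if (length(active) <= 100)
    stop("fewer than 100 head voxels under the priors")
  Pa <- P[active, , drop = FALSE]
  logP <- array(-1e30, dim(Pa))  # hard zeros stay hard in the posterior
  logP[Pa > 0] <- log(Pa[Pa > 0])
  y <- as.vector(vol$data)[active]
  brain <- as.vector(priors$brain_mask$data)[active] > 0

  rng <- range(y[brain])
  # second term: numerical floor relative to the intensity scale, so that
  # cancellation noise in the moment computations cannot differentiate
  # components on (near-)degenerate inputs
  varfloor <- max((config$variance_floor_frac * diff(rng))^2,
                  (1e-6 * max(abs(rng), 1))^2)
  cold <- init_mixture(y, Pa, classes, config$n_gaussians, brain, varfloor)
  comps <- if (!is.null(init_model)) {
    warm <- init_model$comps[c("class", "w", "mu", "s2")]
    warm$s2 <- pmax(warm$s2, varfloor)
    for (k in reinit_classes)
      warm[warm$class == k, ] <- cold[cold$class == k, ]
    warm
  } else cold
  cls0 <- match(comps$class, classes) - 1L

  # bias-field basis over the head support, centred on the brain
  use_bias <- config$bias_degree > 0
  if (use_bias) {
    xyz <- voxel_grid_world(vol)[active, , drop = FALSE]
    X <- poly_basis_3d(xyz, config$bias_degree)
    fit_rows <- which(brain & y > 0)
  }
  logb <- numeric(length(y))
  bias_coef <- NULL

  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      clipped = logical(0), bias_updated = logical(0))
  ll_prev <- -Inf
  converged <- FALSE
  bias_frozen <- FALSE
  model <- NULL

  for (it in seq_len(config$em_max_iter)) {
    yc <- y * exp(-logb)
    bias_due <- use_bias && !bias_frozen &&
      it %% config$bias_interval == 0
    st <- em_step_cpp(yc, logP, cls0, log(comps$w), comps$mu, comps$s2,
                      want_post = FALSE, want_tlog = bias_due)
    ll <- st$loglik - sum(logb)

    # M-step
    ok <- st$N > 1e-8
    comps$mu[ok] <- st$Sy[ok] / st$N[ok]
    for (k in classes) {
      sel <- comps$class == k
      tot <- sum(st$N[sel])
      if (tot > 1) comps$w[sel] <- pmax(st$N[sel], 1e-12) / tot
    }
    comps$N <- st$N
    collapsed <- vapply(classes, function(k)
      sum(st$N[comps$class == k]) < 1, logical(1))

    # constraint projection (meaningless without any intensity contrast)
    clipped <- FALSE
    if (all(c("GWM", "CSF", "CMB") %in% classes) && diff(rng) > 0) {
      g <- posterior_weighted_gwm_mean(comps)
      m0 <- structure(list(comps = comps, gwm_mean = g),
                      class = "mixture_model")
      m0 <- constrain_means(m0, config$constraint_eps)
      clipped <- attr(m0, "clipped")
      comps <- m0$comps
    }
    # variance update. Default: standard M-step about the raw means (the
    # clip is applied afterwards), which keeps the CMB class tight around
    # genuinely dark intensities. With constrained_variance the second
    # moment is taken about the projected means — the constrained MLE —
    # so a clipped component stays broad enough to keep holding the
    # voxels it explains (used in the second pass, where the CMB prior
    # territory is already vetted).
    mu_ref <- if (constrained_variance) comps$mu else st$Sy / st$N
    comps$s2[ok] <- pmax(
      st$Syy[ok] / st$N[ok] -
        2 * mu_ref[ok] * st$Sy[ok] / st$N[ok] + mu_ref[ok]^2,
      varfloor)

    # bias update: precision-weighted least squares of the log-residual
    # (log y - current log-field - responsibility-weighted log class mean)
    # onto the polynomial basis; frozen once an update stops moving it
    bias_updated <- FALSE
    if (bias_due) {
      t_res <- log(pmax(y, 1e-12)) - logb - st$tlogmu
      cf <- tryCatch(
        robust_wls(X[fit_rows, , drop = FALSE], t_res[fit_rows],
                   st$wprec[fit_rows]),
        error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        f <- logb + as.vector(X %*% cf)
        f <- f - mean(f[brain])
        delta <- max(abs(f - logb))
        logb <- f
        bias_coef <- cf
        bias_updated <- TRUE
        if (delta < 1e-3) bias_frozen <- TRUE
      }
    }

    trace <- rbind(trace, data.frame(iter = it, loglik = ll,
                                     clipped = clipped,
                                     bias_updated = bias_updated))
    if (it >= 3 && is.finite(ll_prev) &&
        abs(ll - ll_prev) <= config$em_tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged)
    warning("EM did not converge in ", config$em_max_iter,
            " iterations; returning current state")

  # final E-step with projected parameters; iterate the projection until the
  # constraints hold exactly against the returned posteriors themselves
  yc <- y * exp(-logb)
  full_set <- all(c("GWM", "CSF", "CMB") %in% classes) && diff(rng) > 0
  g <- NA_real_
  for (rep in 1:10) {
    st <- em_step_cpp(yc, logP, cls0, log(comps$w), comps$mu, comps$s2,
                      want_post = TRUE, want_tlog = FALSE)
    comps$N <- st$N
    if (!full_set) break
    g <- posterior_weighted_gwm_mean(comps)
    violated <- any(comps$mu[comps$class == "CSF"] <= g) ||
      any(comps$mu[comps$class == "CMB"] >= 0.5 * g)
    if (!violated) break
    m0 <- constrain_means(structure(list(comps = comps, gwm_mean = g),
                                    class = "mixture_model"),
                          config$constraint_eps)
    comps <- m0$comps
  }

  d <- dim(vol$data)
  post_full <- P
  post_full[active, ] <- st$post
  posteriors <- lapply(seq_along(classes), function(k)
    volume3d(array(post_full[, k], d), affine = vol$affine,
             description = paste("posterior:", classes[k])))
  names(posteriors) <- classes

  bias_arr <- array(1, d)
  bias_arr[active] <- exp(logb)
  bias <- structure(list(coef = bias_coef, degree = config$bias_degree,
                         field = volume3d(bias_arr, affine = vol$affine,
                                          description = "bias field")),
                    class = "bias_field")

  model <- structure(list(classes = classes,
                          n_gaussians = config$n_gaussians,
                          comps = comps, gwm_mean = g, trace = trace,
                          converged = converged, collapsed = collapsed),
                     class = "mixture_model")
  structure(list(model = model, posteriors = posteriors, bias = bias),
            class = "midas_fit")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: %d Gaussians over %d classes, GWM mean %.3g\n",
              nrow(x$comps), length(x$classes), x$gwm_mean))
  print(x$comps, row.names = FALSE)
  invisible(x)
}

#' Estimate a multiplicative bias field from posteriors
#'
#' Weighted least-squares fit of the per-voxel log-residual (log intensity
#' minus posterior-weighted log class mean) onto a low-order 3D polynomial
#' basis; the fitted log-field is mean-centred over the mask and
#' exponentiated. If the basis is ill-conditioned the order is reduced with
#' a warning.
#'
#' @param vol a [volume3d].
#' @param posteriors named list of class posterior [volume3d]s (weights).
#' @param class_means named vector of class mean intensities, or a
#'   `mixture_model` from which they are derived.
#' @param degree polynomial degree (default 3).
#' @param mask logical/0-1 array of voxels to fit and centre over (default:
#'   voxels with positive intensity and total posterior weight).
#' @return A `bias_field` (coefficients + realised field).
#' @export
estimate_bias <- function(vol, posteriors, class_means, degree = 3L,
                          mask = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  if (inherits(class_means, "mixture_model")) {
    cm <- vapply(class_means$classes, function(k) {
      sel <- class_means$comps$class == k
      sum(class_means$comps$w[sel] * class_means$comps$mu[sel])
    }, numeric(1))
    class_means <- cm
  }
  ks <- intersect(names(posteriors), names(class_means))
  W <- vapply(posteriors[ks], function(m) as.vector(m$data),
              numeric(length(vol$data)))
  pred_log <- as.vector(W %*% log(pmax(class_means[ks], 1e-12)))
  wtot <- rowSums(W)
  y <- as.vector(vol$data)
  msk <- if (is.null(mask)) wtot > 0.5 & y > 0 else
    as.vector(mask) > 0 & y > 0
  t_res <- log(pmax(y, 1e-12)) - pred_log / pmax(wtot, 1e-12)
  xyz <- voxel_grid_world(vol)
  for (deg in seq(degree, 1)) {
    X <- poly_basis_3d(xyz[msk, , drop = FALSE], deg)
    cf <- tryCatch(robust_wls(X, t_res[msk], wtot[msk]),
                   error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) {
      if (deg < degree) warning("bias basis reduced to degree ", deg)
      Xall <- poly_basis_3d(xyz, deg, scale_to = attr(X, "scale_to"))
      f <- as.vector(Xall %*% cf)
      f <- f - mean(f[msk])
      return(structure(list(coef = cf, degree = deg,
                            field = volume3d(array(exp(f), dim(vol$data)),
                                             affine = vol$affine,
                                             description = "bias field")),
                       class = "bias_field"))
    }
  }
  stop("bias basis ill-conditioned at every degree")
}
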