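# single-class, single-Gaussian prior set over a bare grid: the EM must
# reduce to the closed-form sample mean / variance
flat_one_class_priors <- function(dim, affine) {
  maps <- list(GWM = volume3d(array(1, dim), affine = affine))
  bm <- volume3d(array(1L, dim), affine = affine)
  midas:::new_prior_set(maps, bm, 1e-6)
}

test_that("one-class flat-prior fit equals the closed-form sample moments", {
  set.seed(8)
  d <- c(12, 12, 6)
  v <- volume3d(array(rnorm(prod(d), 50, 8), d), spacing = c(2, 2, 2))
  pr <- flat_one_class_priors(d, v$affine)
  cfg <- midas_config(n_gaussians = c(GWM = 1L), bias_degree = 0,
                      variance_floor_frac = 1e-6, em_tol = 1e-12,
                      em_max_iter = 50)
  fit <- suppressWarnings(fit_constrained_mixture(v, pr, cfg))
  y <- as.vector(v$data)
  expect_equal(fit$model$comps$mu, mean(y), tolerance = 1e-6)
  expect_equal(fit$model$comps$s2, mean((y - mean(y))^2), tolerance = 1e-6)
  expect_equal(max(abs(fit$posteriors$GWM$data - 1)), 0)
})

test_that("constant-intensity volumes converge with posteriors equal to the priors", {
  ph <- small_phantom(seed = 9, grid_shape = c(36, 36, 8), noise_sigma = 0)
  pr <- priors_from_labels(ph$truth$labels)
  const <- ph$volume
  const$data[] <- 42
  fit <- suppressWarnings(
    fit_constrained_mixture(const, pr, midas_config(bias_degree = 0)))
  P <- midas:::prior_matrix(pr)
  post <- vapply(fit$posteriors, function(m) as.vector(m$data),
                 numeric(nrow(P)))
  # the likelihood carries no information, so responsibilities follow the
  # priors; the variance floor keeps every Gaussian proper
  expect_lt(max(abs(post - P[, colnames(post)])), 1e-6)
  expect_true(all(fit$model$comps$s2 >=
                    midas_config()$variance_floor_frac^2 * 0))
})

test_that("mean constraints clip exactly as specified", {
  comps <- data.frame(
    class = c("GWM", "GWM", "CSF", "CSF", "CMB", "CMB"),
    w = rep(0.5, 6),
    mu = c(95, 105, 150, 90, 80, 30),
    s2 = rep(25, 6),
    N = c(500, 500, 200, 200, 10, 10))
  model <- structure(list(comps = comps, gwm_mean = 100),
                     class = "mixture_model")
  out <- constrain_means(model, eps = 1e-3)
  expect_true(attr(out, "clipped"))
  expect_equal(out$comps$mu[3], 150)                 # already valid
  expect_equal(out$comps$mu[4], 100 * (1 + 1e-3))    # clipped up
  expect_equal(out$comps$mu[5], 50 * (1 - 1e-3))     # 0.8 gwm -> 0.4995 gwm
  expect_equal(out$comps$mu[6], 30)                  # already valid

  ok <- structure(list(comps = transform(comps, mu = c(95, 105, 150, 160,
                                                       45, 30)),
                       gwm_mean = 100), class = "mixture_model")
  out2 <- constrain_means(ok)
  expect_false(attr(out2, "clipped"))
  expect_equal(out2$comps$mu, c(95, 105, 150, 160, 45, 30))
})

test_that("fitted models satisfy the hard mean constraints on phantom data", {
  ph <- small_phantom(seed = 10, bias_amplitude = 0.1)
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(ph$volume, 1.5)
  wp <- midas:::resample_priors(pr, w)
  fit <- fit_constrained_mixture(w, wp)
  cm <- fit$model$comps
  g <- fit$model$gwm_mean
  expect_lt(max(cm$mu[cm$class == "CMB"]), 0.5 * g)
  expect_gt(min(cm$mu[cm$class == "CSF"]), g)
  # gwm_mean is the posterior-weighted mean of the GWM class
  expect_equal(g, midas:::posterior_weighted_gwm_mean(cm))
})

test_that("EM log-likelihood is monotone between projection/bias events", {
  ph <- small_phantom(seed = 12, noise_sigma = 5, bias_amplitude = 0)
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(ph$volume, 1.5)
  wp <- midas:::resample_priors(pr, w)
  fit <- suppressWarnings(
    fit_constrained_mixture(w, wp, midas_config(bias_degree = 0)))
  tr <- fit$model$trace
  dll <- diff(tr$loglik)
  events <- tr$clipped[-1] | tr$bias_updated[-1] | tr$clipped[-nrow(tr)] |
    tr$bias_updated[-nrow(tr)]
  expect_true(all(dll[!events] >= -1e-8 * abs(tr$loglik[-1][!events])))
})

test_that("within-class Gaussian relabelling leaves class posteriors unchanged", {
  ph <- small_phantom(seed = 13, grid_shape = c(36, 36, 8))
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(ph$volume, 3)
  wp <- midas:::resample_priors(pr, w)
  cfg <- midas_config(bias_degree = 0, em_max_iter = 10)
  fit <- suppressWarnings(fit_constrained_mixture(w, wp, cfg))

  swap <- fit$model
  gwm_rows <- which(swap$comps$class == "GWM")
  swap$comps[gwm_rows, ] <- swap$comps[rev(gwm_rows), ]
  refit <- suppressWarnings(
    fit_constrained_mixture(w, wp, midas_config(bias_degree = 0,
                                                em_max_iter = 1),
                            init_model = swap))
  base <- suppressWarnings(
    fit_constrained_mixture(w, wp, midas_config(bias_degree = 0,
                                                em_max_iter = 1),
                            init_model = fit$model))
  for (k in names(base$posteriors))
    expect_equal(refit$posteriors[[k]]$data, base$posteriors[[k]]$data,
                 tolerance = 1e-9)
})

test_that("phantom class means are recovered within 5%", {
  ph <- recovery_phantom(seed = 11, noise_sigma = 5, bias_amplitude = 0)
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(ph$volume, 1.5)
  wp <- midas:::resample_priors(pr, w)
  fit <- fit_constrained_mixture(w, wp)
  lab <- resample_to_grid(ph$truth$labels, w, "nearest")

  class_mean <- function(model, k) {
    sel <- model$comps$class == k
    sum(model$comps$N[sel] * model$comps$mu[sel]) / sum(model$comps$N[sel])
  }
  # reference: sample means of the working-grid intensities under the
  # ground-truth labels; the brain tissue classes are the ones the
  # detection depends on (the peri-cerebral "skull"/"scalp" classes are
  # deliberately loose catch-alls)
  for (k in c("GWM", "CSF")) {
    code <- midas:::PHANTOM_CLASSES[[k]]
    ref <- mean(w$data[lab$data == code])
    expect_lt(abs(class_mean(fit$model, k) - ref) / ref, 0.05)
  }
})

test_that("bias fields are recovered and null fields stay null", {
  # null recovery: unbiased phantom, fitted field within 2% of 1 over brain
  ph0 <- recovery_phantom(seed = 14, noise_sigma = 5, bias_amplitude = 0)
  pr0 <- priors_from_labels(ph0$truth$labels)
  w0 <- resample_isotropic(ph0$volume, 1.5)
  wp0 <- midas:::resample_priors(pr0, w0)
  fit0 <- fit_constrained_mixture(w0, wp0)
  brain0 <- resample_to_grid(ph0$truth$brain_mask, w0, "nearest")$data > 0.5
  expect_lt(max(abs(fit0$bias$field$data[brain0] - 1)), 0.02)

  # imposed 20% linear bias recovered with max error < 5% over the brain
  spec <- phantom_spec(grid_shape = c(120, 120, 17), noise_sigma = 5,
                       bias_amplitude = 0, seed = 15)
  ph <- make_phantom(spec)
  bf <- apply_bias_field(ph$volume, 0.2, seed = 99, degree = 1,
                         mask = ph$truth$brain_mask$data)
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(bf$volume, 1.5)
  wp <- midas:::resample_priors(pr, w)
  fit <- fit_constrained_mixture(w, wp)
  truth <- resample_to_grid(bf$field, w, "linear")
  brain <- resample_to_grid(ph$truth$brain_mask, w, "nearest")$data > 0.5
  ratio <- fit$bias$field$data[brain] / truth$data[brain]
  ratio <- ratio / exp(mean(log(ratio)))
  expect_gt(stats::cor(log(fit$bias$field$data[brain]),
                       log(truth$data[brain])), 0.9)
  expect_lt(max(abs(ratio - 1)), 0.05)

  # bias correction then refit: the trace objective does not collapse
  expect_gt(utils::tail(fit$model$trace$loglik, 1),
            fit$model$trace$loglik[1])
})

test_that("standalone bias estimation works from posteriors and reduces degree when degenerate", {
  spec <- phantom_spec(grid_shape = c(120, 120, 17), noise_sigma = 2,
                       bias_amplitude = 0, seed = 16)
  ph <- make_phantom(spec)
  bf <- apply_bias_field(ph$volume, 0.2, seed = 7, degree = 2,
                         mask = ph$truth$brain_mask$data)
  lab <- ph$truth$labels
  classes <- midas:::PHANTOM_CLASSES
  posts <- lapply(names(classes), function(k)
    volume3d(array(as.numeric(lab$data == classes[[k]]), dim(lab$data)),
             affine = lab$affine))
  names(posts) <- names(classes)
  cm <- c(GWM = 100, CSF = 180, skull = 30, scalp = 140, other = 5)
  eb <- estimate_bias(bf$volume, posts[names(cm)], cm, degree = 3,
                      mask = ph$truth$brain_mask$data)
  brain <- ph$truth$brain_mask$data > 0
  ratio <- eb$field$data[brain] / bf$field$data[brain]
  ratio <- ratio / exp(mean(log(ratio)))
  expect_lt(max(abs(ratio - 1)), 0.05)
})
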