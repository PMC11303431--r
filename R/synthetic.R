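# Synthetic cohorts with recorded ground truth. The default scale mirrors the
# kind of plaque-cohort study the pipeline targets: ~40 samples, a handful of
# latent co-expression modules of ~50 features each embedded among a majority
# of unstructured features, traits tied to module factors at a configurable
# correlation, and a smaller "peptide" matrix carrying linear and purely
# nonlinear responses to one trait.
#
# Factor model: feature g in module m is x_g = beta * f_m + eps,
# eps ~ N(0, noise_sd^2), f_m ~ N(0, 1) i.i.d. per module. The population
# within-module correlation is beta^2 / (beta^2 + noise_sd^2) and the
# correlation of x_g with the factor is beta / sqrt(beta^2 + noise_sd^2).

#' Generate a modular expression cohort
#'
#' @param n_samples Number of samples (default 40; >= 8).
#' @param module_sizes Integer vector of planted module sizes (default five
#'   modules of 50).
#' @param loading Factor loading beta in (0, 1\] shared by module features
#'   (default 0.8).
#' @param noise_sd Feature noise standard deviation (default 0.6).
#' @param n_noise_features Count of pure-noise features (default 750).
#' @param hub_loading Optional loading in (0, 1) given to the first feature
#'   of every module, planting one designated hub gene per module; `NULL`
#'   (default) keeps all loadings equal. The hub's noise sd is
#'   `sqrt(1 - hub_loading^2)`, keeping the unit-variance convention of the
#'   defaults (`0.8^2 + 0.6^2 = 1`), so a loading is the feature's population
#'   correlation with its module factor.
#' @param seed Integer seed; the generator is bit-reproducible from it
#'   (R Mersenne-Twister).
#' @return List with `expression` (matrix, samples x features, each feature
#'   standardized) and `truth` (a `coex_truth` list: `membership` tibble with
#'   `feature_id`, `module`, `loading`; `factors` matrix samples x modules;
#'   `seed`).
#' @export
generate_modular_expression <- function(n_samples = 40,
                                        module_sizes = rep(50, 5),
                                        loading = 0.8,
                                        noise_sd = 0.6,
                                        n_noise_features = 750,
                                        hub_loading = NULL,
                                        seed = 1) {
  if (n_samples < 8) abort("n_samples must be >= 8")
  if (loading <= 0 || loading > 1) abort("loading must lie in (0, 1]")
  if (!is.null(hub_loading) && (hub_loading <= 0 || hub_loading > 1)) {
    abort("hub_loading must lie in (0, 1]")
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n_mod <- length(module_sizes)
  modules <- paste0("M", seq_len(n_mod))
  factors <- matrix(rnorm(n_samples * n_mod), n_samples, n_mod,
                    dimnames = list(sprintf("S%03d", seq_len(n_samples)), modules))
  p <- sum(module_sizes) + n_noise_features
  ids <- sprintf("G%05d", seq_len(p))
  membership <- rep(c(modules, GREY_LABEL), c(module_sizes, n_noise_features))
  betas <- ifelse(membership == GREY_LABEL, 0, loading)
  sds <- ifelse(membership == GREY_LABEL, 1, noise_sd)
  if (!is.null(hub_loading)) {
    hub_idx <- cumsum(c(1, head(module_sizes, -1)))  # first feature per module
    betas[hub_idx] <- hub_loading
    sds[hub_idx] <- sqrt(1 - hub_loading^2)
  }
  x <- matrix(rnorm(n_samples * p), n_samples, p,
              dimnames = list(rownames(factors), ids))
  planted <- which(membership != GREY_LABEL)
  for (g in planted) {
    x[, g] <- betas[g] * factors[, membership[g]] + rnorm(n_samples, sd = sds[g])
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  truth <- structure(list(
    membership = tibble(feature_id = ids, module = membership,
                        loading = betas),
    factors = factors,
    seed = seed
  ), class = "coex_truth")
  list(expression = x, truth = truth)
}

#' Generate traits linked to planted module factors
#'
#' A linked trait is `rho * f_m + sqrt(1 - rho^2) * N(0, 1)`, so its
#' population correlation with the module factor is exactly `rho`. Null traits
#' are independent standard normal. An optional missing-at-random mask blanks
#' cells at the given rate.
#'
#' @param truth A `coex_truth` object from [generate_modular_expression()].
#' @param links Named list mapping trait name to `list(module =, rho =)`;
#'   default plants an MVD-like trait on module M1 at rho 0.7.
#' @param n_null_traits Count of unlinked traits (default 4).
#' @param missing_rate Missing-at-random fraction in \[0, 1) (default 0).
#' @param seed Integer seed.
#' @return Trait tibble (`sample_id` + one numeric column per trait).
#' @export
generate_traits <- function(truth,
                            links = list(MVD = list(module = "M1", rho = 0.7)),
                            n_null_traits = 4,
                            missing_rate = 0,
                            seed = 1) {
  stopifnot(inherits(truth, "coex_truth"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  f <- truth$factors
  n <- nrow(f)
  cols <- list()
  for (nm in names(links)) {
    link <- links[[nm]]
    if (!link$module %in% colnames(f)) {
      abort(sprintf("linked module '%s' not planted", link$module))
    }
    if (abs(link$rho) >= 1) abort("|rho| must be < 1 (use a feature directly for rho = 1)")
    cols[[nm]] <- link$rho * f[, link$module] +
      sqrt(1 - link$rho^2) * rnorm(n)
  }
  for (i in seq_len(n_null_traits)) {
    cols[[sprintf("null_%d", i)]] <- rnorm(n)
  }
  out <- tibble(sample_id = rownames(f), !!!cols)
  if (missing_rate > 0) {
    for (nm in names(cols)) {
      mask <- runif(n) < missing_rate
      out[[nm]][mask] <- NA_real_
    }
  }
  out
}

#' Zero-centered, exactly symmetric target vector
#'
#' Mirrored uniform draws: `t = c(u, -u)` with `u ~ U(0, sqrt(3))`, giving a
#' zero-mean, unit-variance sample that is exactly symmetric, so every odd
#' sample moment vanishes and a purely quadratic response is orthogonal to the
#' target in-sample. Odd lengths get one exact zero.
#'
#' @param n_samples Target length (>= 8).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
symmetric_target <- function(n_samples = 40, seed = 1) {
  if (n_samples < 8) abort("n_samples must be >= 8")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  half <- runif(floor(n_samples / 2), 0, sqrt(3))
  t <- c(half, -half)
  if (n_samples %% 2 == 1) t <- c(t, 0)
  t
}

#' Generate a peptide matrix with planted functional responses
#'
#' Plants features that respond to the target linearly (`t + eps`), as a pure
#' parabola (`(t - mean(t))^2 + eps`, uncorrelated with a symmetric target)
#' or as a sinusoid (`sin(omega * t) + eps`), among independent noise
#' features.
#'
#' @param target Numeric trait vector (>= 8 samples); see
#'   [symmetric_target()].
#' @param n_linear,n_parabola,n_sinusoid,n_noise Feature counts (defaults
#'   5 / 5 / 0 / 190).
#' @param noise_sd Feature noise sd (default 0.3).
#' @param omega Sinusoid frequency (default 3).
#' @param seed Integer seed.
#' @return List with `peptides` (matrix, samples x features) and `truth`
#'   (tibble: `feature_id`, `class`, `noise_sd`).
#' @export
generate_peptides <- function(target, n_linear = 5, n_parabola = 5,
                              n_sinusoid = 0, n_noise = 190,
                              noise_sd = 0.3, omega = 3, seed = 1) {
  n <- length(target)
  if (n < 8) abort("target must have >= 8 samples")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  classes <- rep(c("linear", "parabola", "sinusoid", "noise"),
                 c(n_linear, n_parabola, n_sinusoid, n_noise))
  p <- length(classes)
  ids <- sprintf("P%04d", seq_len(p))
  x <- matrix(NA_real_, n, p, dimnames = list(names(target) %||%
                                                sprintf("S%03d", seq_len(n)), ids))
  centred <- target - mean(target)
  for (j in seq_len(p)) {
    x[, j] <- switch(classes[j],
      linear   = target + rnorm(n, sd = noise_sd),
      parabola = centred^2 + rnorm(n, sd = noise_sd),
      sinusoid = sin(omega * target) + rnorm(n, sd = noise_sd),
      noise    = rnorm(n)
    )
  }
  list(peptides = x,
       truth = tibble(feature_id = ids, class = classes,
                      noise_sd = ifelse(classes == "noise", 1, noise_sd)))
}

#' @export
#' @method print coex_truth
print.coex_truth <- function(x, ...) {
  planted <- x$membership$module != GREY_LABEL
  cat(sprintf("<coex_truth> %d planted features in %d modules + %d noise features, seed %d\n",
              sum(planted), ncol(x$factors), sum(!planted), x$seed))
  invisible(x)
}
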