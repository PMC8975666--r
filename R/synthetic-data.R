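#' The 16-variable prognostic catalog
#'
#' The candidate clinical variables screened for the prognosis model: twelve
#' discrete factors and four continuous measurements (diagnosis age, tumor
#' size, examined lymph-node count, positive lymph-node count).
#'
#' @return data.frame with columns \code{name}, \code{kind}
#'   (\code{"discrete"}/\code{"continuous"}) and \code{levels} (level count,
#'   \code{NA} for continuous variables).
#' @export
variable_catalog <- function() {
  data.frame(
    name = c("gender", "marital_status", "location", "affected_side",
             "pathological_type", "histological_grade", "tumor_stage",
             "metastasis_degree", "diffusion_degree",
             "lymph_node_accumulation", "operation_type", "radiotherapy",
             "diagnosis_age", "tumor_size", "examined_lymph_nodes",
             "positive_lymph_nodes"),
    kind = c(rep("discrete", 12), rep("continuous", 4)),
    levels = c(2L, 2L, 3L, 2L, 3L, 2L, 2L, 3L, 3L, 3L, 3L, 2L,
               NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Default generating ranges and interval counts for the continuous variables.
# Clinically conventional cut points: age at 65 years, tumor size at 5 cm,
# examined nodes at 20, positive nodes in three equal bands of [0, 12].
default_continuous_specs <- function() {
  list(
    diagnosis_age        = discretization_spec(40, 90, 2),
    tumor_size           = discretization_spec(0, 10, 2),
    examined_lymph_nodes = discretization_spec(0, 40, 2),
    positive_lymph_nodes = discretization_spec(0, 12, 2)
  )
}

#' Construct a ground-truth Bayesian network for simulation
#'
#' With no arguments this returns the default seven-node truth: the six final
#' prognostic variables (histological grade, tumor stage, diagnosis age,
#' tumor size, examined and positive lymph-node counts) each a parent of
#' binary survival status, plus one predictor-predictor edge
#' tumor_stage -> positive_lymph_nodes so that conditional-independence
#' search meets a non-trivial conditioning case.  The outcome CPT is additive
#' on the log-odds scale with strong effects (see the methods vignette).
#'
#' @param config optional list with elements \code{levels} (named list of
#'   level labels), \code{parents} (named parent list), \code{cpts} (named
#'   list of CPT matrices, or the string \code{"random"}), \code{outcome},
#'   \code{seed} (required when \code{cpts = "random"}) and
#'   \code{continuous} (named list of [discretization_spec()] giving the
#'   generating range of continuous nodes).
#' @param effect scale multiplier for the default outcome log-odds effects
#'   (1 = the default strong setting; 0 = outcome independent of predictors).
#' @return a validated [bn] object; continuous generating specs are attached
#'   as the \code{continuous} element.
#' @examples
#' net <- make_ground_truth()
#' summary(net)
#' @export
make_ground_truth <- function(config = NULL, effect = 1) {
  if (is.null(config)) config <- default_truth_config(effect)
  cpts <- config$cpts
  if (identical(cpts, "random")) {
    if (is.null(config$seed))
      stop("random CPTs require a 'seed' in the config")
    cpts <- with_seed(config$seed, random_cpts(config$levels, config$parents))
  }
  net <- bn(config$levels, config$parents, cpts, outcome = config$outcome)
  net$continuous <- config$continuous %||% list()
  for (v in names(net$continuous)) {
    sp <- net$continuous[[v]]
    if (sp$r != length(net$levels[[v]]))
      stop("continuous spec for '", v, "' has r = ", sp$r,
           " but the node has ", length(net$levels[[v]]), " levels")
  }
  net
}

default_truth_config <- function(effect = 1) {
  lv <- list(
    histological_grade   = c("low", "high"),
    tumor_stage          = c("IIIB", "IV"),
    diagnosis_age        = c("1", "2"),
    tumor_size           = c("1", "2"),
    examined_lymph_nodes = c("1", "2"),
    positive_lymph_nodes = c("1", "2"),
    survival_status      = c("alive", "dead")
  )
  preds <- setdiff(names(lv), "survival_status")
  parents <- list(positive_lymph_nodes = "tumor_stage",
                  survival_status = preds)
  # log-odds of death contributed by each predictor level
  eff <- list(
    histological_grade   = c(0, 2.1) * effect,
    tumor_stage          = c(0, 2.1) * effect,
    diagnosis_age        = c(0, 1.6) * effect,
    tumor_size           = c(0, 1.6) * effect,
    examined_lymph_nodes = c(0, -1.8) * effect,
    positive_lymph_nodes = c(0, 2.3) * effect
  )
  b0 <- -4.2 * effect                        # keeps P(dead) near 1/2
  cpts <- list(
    histological_grade   = matrix(c(0.45, 0.55), 1),
    tumor_stage          = matrix(c(0.45, 0.55), 1),
    diagnosis_age        = matrix(c(0.5, 0.5), 1),
    tumor_size           = matrix(c(0.55, 0.45), 1),
    examined_lymph_nodes = matrix(c(0.5, 0.5), 1),
    positive_lymph_nodes = rbind(c(0.65, 0.35),
                                 c(0.30, 0.70))
  )
  sizes <- vapply(preds, function(v) length(lv[[v]]), 1L)
  grid <- config_grid(sizes)
  pd <- plogis(b0 + rowSums(vapply(seq_along(preds), function(i) {
    eff[[preds[i]]][grid[, i]]
  }, numeric(nrow(grid)))))
  cpts$survival_status <- cbind(alive = 1 - pd, dead = pd)
  list(levels = lv, parents = parents, cpts = cpts,
       outcome = "survival_status", continuous = default_continuous_specs())
}

random_cpts <- function(levels, parents) {
  lapply(stats::setNames(names(levels), names(levels)), function(v) {
    pa <- parents[[v]] %||% character(0)
    nr <- prod(vapply(pa, function(p) length(levels[[p]]), 1L))
    k <- length(levels[[v]])
    m <- matrix(stats::rgamma(nr * k, shape = 1), nr, k)
    m / rowSums(m)
  })
}

#' Forward-sample a cohort from a ground-truth network
#'
#' Samples \code{n} subjects in topological order: each discrete variable is
#' drawn from its CPT given its sampled parents.  Nodes carrying a continuous
#' generating spec are reported on the continuous scale: the sampled level is
#' mapped to a uniform draw inside that level's equidistant interval, so that
#' [equidistant_discretize()] with the same spec recovers the level exactly.
#'
#' @param net a [bn] with CPTs (e.g. from [make_ground_truth()]).
#' @param n number of rows.
#' @param seed RNG seed.
#' @return data.frame with one row per subject; discrete variables are
#'   factors, continuous ones numeric.  The sampled discrete levels of every
#'   node (including continuous ones) are attached as attribute
#'   \code{"levels"}.
#' @export
sample_cohort <- function(net, n, seed = 1L) {
  stop_if_not_scalar_count(n)
  if (is.null(net$cpts)) stop("network has no CPTs to sample from")
  ord <- topo_sort(net$nodes, net$parents)
  lev <- matrix(NA_integer_, n, length(net$nodes),
                dimnames = list(NULL, net$nodes))
  with_seed(seed, {
    for (v in ord) {
      pa <- net$parents[[v]]
      cpt <- net$cpts[[v]]
      if (length(pa) == 0L) {
        lev[, v] <- sample.int(ncol(cpt), n, replace = TRUE, prob = cpt[1, ])
      } else {
        sizes <- vapply(pa, function(p) length(net$levels[[p]]), 1L)
        rows <- apply(lev[, pa, drop = FALSE], 1L, config_index, sizes = sizes)
        u <- stats::runif(n)
        cum <- t(apply(cpt, 1L, cumsum))
        lev[, v] <- rowSums(u > cum[rows, , drop = FALSE]) + 1L
      }
    }
    out <- as.data.frame(lapply(stats::setNames(net$nodes, net$nodes),
                                function(v) {
      sp <- net$continuous[[v]]
      if (is.null(sp)) {
        factor(net$levels[[v]][lev[, v]], levels = net$levels[[v]])
      } else {
        j <- lev[, v] - 1L                       # level index, 0-based
        lo <- sp$x_min + j * sp$d
        # uniform strictly inside (lo, lo + d] so discretization inverts
        lo + sp$d * stats::runif(n, min = .Machine$double.eps, max = 1)
      }
    }))
    attr(out, "levels") <- as.data.frame(lapply(
      stats::setNames(net$nodes, net$nodes),
      function(v) factor(net$levels[[v]][lev[, v]], levels = net$levels[[v]])))
    out
  })
}

#' @rdname sample_cohort
#' @param object,nsim,... [stats::simulate()] interface: \code{simulate(net,
#'   nsim = n, seed = s)} is equivalent to \code{sample_cohort(net, n, s)}.
#' @export
simulate.bn <- function(object, nsim = 1, seed = 1L, ...) {
  sample_cohort(object, nsim, seed)
}

#' Exact marginal distribution of each node by CPT enumeration
#'
#' Used as the independent truth that forward-sampled frequencies must
#' approach.  Enumerates the full joint over all configurations.
#'
#' @param net a [bn] with CPTs.
#' @return named list of marginal probability vectors.
#' @export
exact_marginals <- function(net) {
  sizes <- vapply(net$nodes, function(v) length(net$levels[[v]]), 1L)
  grid <- config_grid(sizes)
  colnames(grid) <- net$nodes
  p <- joint_probability(net, grid)
  lapply(stats::setNames(net$nodes, net$nodes), function(v) {
    m <- vapply(seq_len(sizes[[v]]),
                function(l) sum(p[grid[, v] == l]), 0)
    stats::setNames(m, net$levels[[v]])
  })
}

# Probability of each full configuration (rows of integer level matrix).
joint_probability <- function(net, grid) {
  p <- rep(1, nrow(grid))
  for (v in net$nodes) {
    pa <- net$parents[[v]]
    cpt <- net$cpts[[v]]
    if (length(pa) == 0L) {
      p <- p * cpt[1L, grid[, v]]
    } else {
      sizes <- vapply(pa, function(q) length(net$levels[[q]]), 1L)
      rows <- apply(grid[, pa, drop = FALSE], 1L, config_index, sizes = sizes)
      p <- p * cpt[cbind(rows, grid[, v])]
    }
  }
  p
}

#' Add independent nuisance variables from the full catalog
#'
#' Extends a sampled cohort with the catalog variables that are not part of
#' the generating network, drawn independently of everything else; these are
#' the variables a chi-square screen should discard.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param seed RNG seed.
#' @return the cohort with the extra factor columns appended.
#' @export
add_nuisance_variables <- function(cohort, seed = 1L) {
  cat <- variable_catalog()
  extra <- cat[cat$kind == "discrete" & !cat$name %in% names(cohort), ]
  with_seed(seed, {
    for (i in seq_len(nrow(extra))) {
      k <- extra$levels[i]
      cohort[[extra$name[i]]] <- factor(
        sample.int(k, nrow(cohort), replace = TRUE),
        levels = seq_len(k))
    }
    cohort
  })
}

#' Phantom specification
#'
#' Geometry and noise model of a synthetic lesion image stack: a homogeneous
#' ellipsoidal lesion on a uniform background with additive Gaussian noise.
#'
#' @param shape integer grid dimensions (slices, rows, cols).
#' @param spacing voxel spacing in mm per axis (slice, row, col).
#' @param center lesion center in mm, measured from the volume corner.
#' @param semiaxes ellipsoid semi-axes in mm (slice, row, col axes).
#' @param background,lesion mean intensities in [0, 255].
#' @param noise_sd Gaussian noise standard deviation (intensity levels).
#' @param seed RNG seed for the noise field.
#' @export
phantom_spec <- function(shape = c(21L, 64L, 64L), spacing = c(1, 1, 1),
                         center = shape * spacing / 2, semiaxes = c(10, 10, 10),
                         background = 60, lesion = 160, noise_sd = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive sizes")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(semiaxes <= 0)) stop("semi-axes must be positive")
  if (any(c(background, lesion) < 0) || any(c(background, lesion) > 255))
    stop("intensities must lie in [0, 255]")
  ext <- shape * spacing
  if (any(center - semiaxes < 0) || any(center + semiaxes > ext))
    stop("lesion extends outside the image grid")
  structure(list(shape = shape, spacing = spacing, center = center,
                 semiaxes = semiaxes, background = background,
                 lesion = lesion, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' Generate a lesion phantom with known geometry
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{image} (3D array of 8-bit intensities, dims
#'   slices x rows x cols), \code{mask} (logical ellipsoid membership),
#'   \code{truth} (a \code{lesion_measurement} holding the analytic longest
#'   in-plane diameter 2*max(row, col semi-axis) in mm and the analytic
#'   ellipsoid volume 4/3*pi*a*b*c in cm^3) and \code{spec}.
#' @examples
#' ph <- make_phantom(phantom_spec(semiaxes = c(10, 10, 10)))
#' ph$truth$volume_cm3   # 4.18879
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  cc <- lapply(1:3, function(a) ((seq_len(d[a]) - 0.5) * spec$spacing[a]))
  z <- outer((cc[[1]] - spec$center[1])^2 / spec$semiaxes[1]^2,
             (cc[[2]] - spec$center[2])^2 / spec$semiaxes[2]^2, "+")
  q <- outer(z, (cc[[3]] - spec$center[3])^2 / spec$semiaxes[3]^2, "+")
  mask <- q <= 1
  img <- array(spec$background, dim = d)
  img[mask] <- spec$lesion
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  }
  img <- pmin(pmax(img, 0), 255)
  truth <- lesion_measurement(
    diameter_mm = 2 * max(spec$semiaxes[2:3]),
    volume_cm3 = 4 / 3 * pi * prod(spec$semiaxes) / 1000,
    n_voxels = sum(mask))
  list(image = img, mask = mask, truth = truth, spec = spec)
}

#' Two-arm follow-up specification and simulation
#'
#' Event times are exponential with the arm's hazard (1/months); times beyond
#' the administrative censoring time are censored there.
#'
#' @param hazards named numeric vector of per-arm event hazards (> 0).
#' @param censor_time administrative censoring time in months (Inf for none).
#' @param arm_sizes named integer vector of per-arm subject counts.
#' @param seed RNG seed.
#' @export
followup_spec <- function(hazards = c(control = log(2) / 4.8,
                                      research = log(2) / 7.1),
                          censor_time = 24, arm_sizes = c(control = 20,
                                                          research = 20),
                          seed = 1L) {
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (any(arm_sizes < 1)) stop("arm sizes must be positive")
  structure(list(hazards = hazards, censor_time = censor_time,
                 arm_sizes = stats::setNames(as.integer(arm_sizes),
                                             names(arm_sizes)),
                 seed = seed),
            class = "followup_spec")
}

#' @rdname followup_spec
#' @param spec a \code{followup_spec}.
#' @return data.frame with columns \code{arm}, \code{time} (months) and
#'   \code{event} (1 = progression observed, 0 = censored).
#' @export
simulate_followup <- function(spec) {
  stopifnot(inherits(spec, "followup_spec"))
  arms <- names(spec$arm_sizes)
  with_seed(spec$seed, {
    out <- do.call(rbind, lapply(arms, function(a) {
      t_ev <- stats::rexp(spec$arm_sizes[[a]], rate = spec$hazards[[a]])
      data.frame(arm = a,
                 time = pmin(t_ev, spec$censor_time),
                 event = as.integer(t_ev <= spec$censor_time))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Fractional Brownian surface fixture
#'
#' Spectral-synthesis fractional Brownian surface with Hurst exponent H,
#' rescaled to 8-bit levels; rougher surfaces (small H) have larger fractal
#' dimension (about 3 - H).
#'
#' @param n side length (power of 2 recommended).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed RNG seed.
#' @return n x n matrix of values in [0, 255].
#' @export
fbm_surface <- function(n = 64, hurst = 0.5, seed = 1L) {
  stopifnot(hurst > 0, hurst < 1)
  with_seed(seed, {
    fr <- stats::fft(matrix(stats::rnorm(n * n), n, n))
    fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    f <- sqrt(outer(fx^2, fx^2, "+"))
    f[1, 1] <- Inf                              # zero the DC amplitude
    amp <- f^(-(hurst + 1))
    surf <- Re(stats::fft(fr * amp, inverse = TRUE)) / (n * n)
    surf <- surf - min(surf)
    if (max(surf) > 0) surf <- surf / max(surf)
    round(surf * 255)
  })
}
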