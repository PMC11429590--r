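# Forward simulation of six-generation phenotypes under any registry model:
# component labels are drawn from the exact Mendelian mixture weights, then
# phenotypes from the component normal distribution. Each generation uses an
# independent RNG substream derived from the master seed and the generation's
# canonical index, so adding or resizing one generation never perturbs the
# draws of another.

#' Simulation configuration
#'
#' @param model Model code from [model_registry()].
#' @param params An [effect_params()] object; must satisfy the model's
#'   constraints.
#' @param n Named vector of per-generation sample sizes (all six
#'   generations, each >= 2).
#' @param seed Integer master seed.
#' @param cross_id Label attached to the simulated dataset.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(model, params, n, seed = 1, cross_id = "sim") {
  struct <- build_structure(model)
  stopifnot(inherits(params, "effect_params"))
  params_to_theta(struct, params$mean)  # validates the constraints
  if (is.null(names(n)) || !setequal(names(n), GENERATIONS)) {
    stop("n must be a named vector covering all six generations", call. = FALSE)
  }
  n <- as.integer(n[GENERATIONS])
  names(n) <- GENERATIONS
  if (any(n < 2L)) stop("all generation sizes must be >= 2", call. = FALSE)
  structure(list(model = model, params = params, n = n,
                 seed = as.integer(seed), cross_id = cross_id),
            class = "sim_config")
}

#' Simulate a six-generation dataset
#'
#' @param config A [sim_config()].
#' @return A [six_gen_dataset()] compatible with [read_dataset()] /
#'   [write_dataset()]; deterministic given `config$seed`.
#' @examples
#' cfg <- sim_config("1MG-A", effect_params(m = 100, da = 20, sigma2_e = 25),
#'                   n = c(P1 = 10, P2 = 10, F1 = 10, F2 = 20,
#'                         BC1P1 = 15, BC1P2 = 15), seed = 42)
#' simulate_cross(cfg)
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  struct <- build_structure(config$model)
  theta <- params_to_theta(struct, config$params$mean)
  comps <- realize_components(struct, theta, config$params$sigma2_e,
                              config$params$sigma2_pg)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  substream <- sample.int(2147483646L, length(GENERATIONS))
  samples <- lapply(seq_along(GENERATIONS), function(gi) {
    g <- GENERATIONS[gi]
    set.seed(substream[gi])
    cm <- comps[[g]]
    n <- config$n[[g]]
    lab <- sample.int(length(cm$weights), n, replace = TRUE,
                      prob = cm$weights)
    x <- stats::rnorm(n, mean = cm$means[lab], sd = sqrt(cm$variance))
    smp <- generation_sample(g, x, cross_id = config$cross_id)
    attr(smp$values, "component") <- lab  # mixture component of each draw
    smp
  })
  six_gen_dataset(samples, cross_id = config$cross_id)
}

#' Load a bundled cross parameterization
#'
#' The package ships two reference parameter sets, `"crossA"` and
#' `"crossB"`, encoding the published MX2-A-AD effect estimates, variance
#' components and generation sample sizes of the two rapeseed vitamin-C
#' crosses; they drive the test suite and the reproduction scripts.
#'
#' @param name `"crossA"` or `"crossB"`, or a path to a JSON file with the
#'   same schema (`model`, `effects`, `sigma2_e`, `sigma2_pg`, `n`).
#' @param seed Seed stored in the resulting configuration.
#' @return A [sim_config()].
#' @examples
#' cross_fixture("crossA")$params$mean[c("m", "da", "db")]
#' @export
cross_fixture <- function(name, seed = 1) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".json"), package = "segjoint")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown fixture '", name, "' (expected crossA or crossB, or a file)",
         call. = FALSE)
  }
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- effect_params(unlist(js$effects), sigma2_e = js$sigma2_e,
                          sigma2_pg = unlist(js$sigma2_pg))
  sim_config(js$model, params, n = unlist(js$n), seed = seed,
             cross_id = js$cross_id %||% name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic moments of one generation's mixture
#'
#' Mean `sum_c pi_c mu_c` and variance
#' `sum_c pi_c (mu_c - mean)^2 + component variance` of the normal mixture a
#' model implies for one generation — the exact targets the simulator's
#' sample moments converge to.
#'
#' @param struct A [build_structure()] object.
#' @param params An [effect_params()].
#' @param generation Generation label.
#' @return Named vector `c(mean, variance)`.
#' @export
mixture_moments <- function(struct, params, generation) {
  theta <- params_to_theta(struct, params$mean)
  cm <- realize_components(struct, theta, params$sigma2_e,
                           params$sigma2_pg)[[generation]]
  mu <- sum(cm$weights * cm$means)
  v <- sum(cm$weights * (cm$means - mu)^2) + cm$variance
  c(mean = mu, variance = v)
}
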