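# Joint maximum-likelihood fitting of a genetic model to a six-generation
# dataset. The likelihood is a product over generations of finite
# normal-mixture likelihoods sharing the genetic-effect parameters through
# the generation design matrices; maximization is by EM with conditional
# maximization steps (IECM): responsibilities -> weighted least squares for
# the mean parameters -> variance updates (sigma2_e pooled across the whole
# design, one sigma2_pg per segregating generation, floored at 0).

#' Effect parameters of a genetic model
#'
#' Bundles the mean-scale genetic effects with the variance parameters.
#' Mean effects are given by name: `m` (population mean), `da`/`ha` and
#' `db`/`hb` (additive/dominance of the two major genes), `i`, `jab`, `jba`,
#' `l` (digenic epistasis), `pd`/`ph` (collective polygene additive `[d]`
#' and dominance `[h]`), `pi`, `pj`, `pl` (collective polygenic epistasis).
#' Unnamed effects default to 0.
#'
#' @param ... Named mean effects (mg/100 g scale).
#' @param sigma2_e Environmental variance (> 0).
#' @param sigma2_pg Named polygenic variances for the segregating
#'   generations `F2`, `BC1P1`, `BC1P2` (each >= 0).
#' @return Object of class `effect_params`.
#' @examples
#' effect_params(m = 100, da = 20, sigma2_e = 25)
#' @export
effect_params <- function(..., sigma2_e = 1,
                          sigma2_pg = c(F2 = 0, BC1P1 = 0, BC1P2 = 0)) {
  eff <- c(...)
  if (length(eff)) {
    bad <- setdiff(names(eff), EFFECT_BASIS)
    if (length(bad) || is.null(names(eff))) {
      stop("unknown effect name(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(EFFECT_BASIS, collapse = ", "),
           call. = FALSE)
    }
  }
  mean <- stats::setNames(numeric(length(EFFECT_BASIS)), EFFECT_BASIS)
  mean[names(eff)] <- as.numeric(eff)
  if (!is.numeric(sigma2_e) || sigma2_e <= 0) {
    stop("sigma2_e must be > 0", call. = FALSE)
  }
  pg <- c(F2 = 0, BC1P1 = 0, BC1P2 = 0)
  if (!is.null(sigma2_pg)) {
    if (is.null(names(sigma2_pg))) names(sigma2_pg) <- SEG_GENERATIONS
    pg[names(sigma2_pg)] <- as.numeric(sigma2_pg)
  }
  if (any(pg < 0)) stop("sigma2_pg must be >= 0", call. = FALSE)
  structure(list(mean = mean, sigma2_e = unname(sigma2_e), sigma2_pg = pg),
            class = "effect_params")
}

# log-sum-exp over the rows of a matrix; safe for |x - mu|/sigma up to ~40.
.row_logsumexp <- function(ld) {
  m <- ld[, 1]
  for (c in 2:ncol(ld)) m <- pmax(m, ld[, c])
  m + log(rowSums(exp(ld - m)))
}

# Per-generation log-density matrix and responsibilities.
.gen_estep <- function(x, weights, means, variance) {
  n <- length(x)
  if (length(means) == 1L) {
    ll <- -0.5 * (log(2 * pi * variance) + (x - means)^2 / variance)
    return(list(loglik = sum(ll), resp = matrix(1, nrow = n, ncol = 1)))
  }
  C <- length(means)
  dev <- rep.int(x, C) - rep(means, each = n)
  ld <- -0.5 / variance * dev * dev +
    rep(log(weights) - 0.5 * log(2 * pi * variance), each = n)
  dim(ld) <- c(n, C)
  ll <- .row_logsumexp(ld)
  list(loglik = sum(ll), resp = exp(ld - ll))
}

#' Joint log-likelihood of a six-generation dataset under a genetic model
#'
#' Sums, over generations and individuals, the log of the normal-mixture
#' density implied by the model structure at the given effect parameters.
#' Uses log-sum-exp so far-out observations do not underflow.
#'
#' @param dataset A [six_gen_dataset()].
#' @param structure A [build_structure()] object (or a model code).
#' @param params An [effect_params()] object satisfying the model's
#'   constraints.
#' @return The joint log-likelihood (scalar).
#' @export
joint_loglik <- function(dataset, structure, params) {
  if (is.character(structure)) structure <- build_structure(structure)
  stopifnot(inherits(dataset, "six_gen_dataset"),
            inherits(params, "effect_params"))
  if (params$sigma2_e <= 0 || any(params$sigma2_pg < 0)) {
    stop("variances must be positive (sigma2_e > 0, sigma2_pg >= 0)",
         call. = FALSE)
  }
  theta <- params_to_theta(structure, params$mean)
  comps <- realize_components(structure, theta, params$sigma2_e,
                              params$sigma2_pg)
  sum(vapply(GENERATIONS, function(g) {
    cm <- comps[[g]]
    .gen_estep(dataset$samples[[g]]$values, cm$weights, cm$means,
               cm$variance)$loglik
  }, numeric(1)))
}

#' EM fitting configuration
#'
#' @param n_starts Number of EM initializations (1 moment-based start plus
#'   `n_starts - 1` jittered starts); the best final likelihood is kept, with
#'   ties broken by the lexicographically smallest `|theta|`.
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Integer seed controlling the jittered starts (deterministic
#'   fits for a given seed).
#' @param fix_pg_variance If non-`NULL`, fixes every segregating-generation
#'   polygenic variance at this value instead of estimating it (useful for
#'   reducing a mixed model to its major-gene skeleton).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 10, tol = 1e-8, max_iter = 2000, seed = 1,
                       fix_pg_variance = NULL) {
  stopifnot(n_starts >= 1, tol > 0, max_iter >= 1)
  structure(list(n_starts = as.integer(n_starts), tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 fix_pg_variance = fix_pg_variance),
            class = "fit_config")
}

# The two major loci of a two-gene model are exchangeable (both segregate
# 1:2:1 / 1:1 with free recombination), so the likelihood is invariant to
# swapping locus labels. Report the locus with the larger additive effect
# as the first major gene.
.canonicalize_loci <- function(struct, theta) {
  if (struct$loci == 2L && all(c("da", "db") %in% struct$par_names) &&
      abs(theta["da"]) < abs(theta["db"])) {
    for (pair in list(c("da", "db"), c("ha", "hb"), c("jab", "jba"))) {
      if (all(pair %in% names(theta))) {
        theta[pair] <- theta[rev(pair)]
      }
    }
  }
  theta
}

# Moment-based initialization: theta from a weighted least-squares match of
# the six observed generation means to the mixture-implied means, sigma2_e
# from the pooled parental/F1 variance, sigma2_pg from the excess variance of
# each segregating generation.
.init_start <- function(prep, struct) {
  gbar <- vapply(prep, function(p) mean(p$x), numeric(1))
  ng <- vapply(prep, function(p) length(p$x), numeric(1))
  # mean of the mixture = (weights' design) theta
  A <- t(vapply(GENERATIONS, function(g) {
    gg <- struct$generations[[g]]
    as.numeric(gg$weights %*% gg$design)
  }, numeric(length(struct$par_names))))
  A <- matrix(A, nrow = 6, dimnames = list(GENERATIONS, struct$par_names))
  W <- ng
  M <- crossprod(A, W * A)
  b <- crossprod(A, W * gbar)
  theta <- tryCatch(as.numeric(solve(M, b)),
                    error = function(e) as.numeric(MASS::ginv(M) %*% b))
  names(theta) <- struct$par_names
  env_g <- c("P1", "P2", "F1")
  s2e <- sum(vapply(env_g, function(g) {
    (length(prep[[g]]$x) - 1) * stats::var(prep[[g]]$x)
  }, numeric(1))) / sum(ng[env_g] - 1)
  pg <- vapply(SEG_GENERATIONS, function(g) {
    max(0, 0.5 * (stats::var(prep[[g]]$x) - s2e))
  }, numeric(1))
  list(theta = theta, s2e = s2e, pg = pg)
}

.jitter_start <- function(start, scale) {
  th <- start$theta + stats::rnorm(length(start$theta), 0, 0.25 * scale)
  names(th) <- names(start$theta)
  list(theta = th,
       s2e = start$s2e * exp(stats::rnorm(1, 0, 0.3)),
       pg = start$pg * exp(stats::rnorm(length(start$pg), 0, 0.3)))
}

# One EM run from one start. Returns the converged state.
.em_run <- function(prep, struct, start, tol, max_iter, var_floor,
                    fix_pg = NULL) {
  theta <- start$theta
  s2e <- max(start$s2e, var_floor)
  has_pg <- struct$polygene != "none"
  pg <- if (has_pg) pmax(start$pg, 0) else c(F2 = 0, BC1P1 = 0, BC1P2 = 0)
  if (!is.null(fix_pg)) pg[] <- fix_pg
  p <- length(theta)
  prev <- -Inf
  starved <- FALSE
  iter <- 0L
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    # E-step at current parameters, accumulating sufficient statistics
    loglik <- 0
    agg <- vector("list", 6)
    names(agg) <- GENERATIONS
    for (g in GENERATIONS) {
      pr <- prep[[g]]
      v <- if (pr$seg && has_pg) s2e + unname(pg[g]) else s2e
      mu <- as.numeric(pr$design %*% theta)
      es <- .gen_estep(pr$x, pr$weights, mu, v)
      loglik <- loglik + es$loglik
      n_c <- colSums(es$resp)
      S_c <- as.numeric(crossprod(es$resp, pr$x))
      agg[[g]] <- list(n_c = n_c, S_c = S_c, v = v, resp = es$resp)
      if (any(n_c < 1) && length(n_c) > 1L) starved <- TRUE
    }
    trace[iter] <- loglik
    if (loglik < prev - 1e-6 * (1 + abs(prev))) {
      warning("EM log-likelihood decreased at iteration ", iter,
              " (", format(prev - loglik), "); keeping previous state")
    }
    # convergence on the Aitken-projected asymptotic log-likelihood: EM's
    # linear convergence rate is estimated from the last three values and
    # the stop fires when the projected remaining gain drops below tol
    done <- FALSE
    if (is.finite(prev) && abs(loglik - prev) < tol) {
      done <- TRUE
    } else if (iter >= 3L) {
      d1 <- trace[iter] - trace[iter - 1L]
      d0 <- trace[iter - 1L] - trace[iter - 2L]
      if (d0 > 0 && d1 > 0 && d1 < d0) {
        rate <- d1 / d0
        if (d1 * rate / (1 - rate) < tol) done <- TRUE
      }
    }
    if (done) {
      return(list(theta = theta, s2e = s2e, pg = pg, loglik = loglik,
                  iter = iter, converged = TRUE, starved = starved,
                  trace = trace))
    }
    if (iter >= max_iter) {
      return(list(theta = theta, s2e = s2e, pg = pg, loglik = loglik,
                  iter = iter, converged = FALSE, starved = starved,
                  trace = trace))
    }
    prev <- loglik
    # CM-step 1: mean parameters by responsibility-weighted least squares
    M <- matrix(0, p, p)
    b <- numeric(p)
    for (g in GENERATIONS) {
      pr <- prep[[g]]
      a <- agg[[g]]
      M <- M + crossprod(pr$design, (a$n_c / a$v) * pr$design)
      b <- b + as.numeric(crossprod(pr$design, a$S_c / a$v))
    }
    theta <- tryCatch(as.numeric(solve(M, b)),
                      error = function(e) as.numeric(MASS::ginv(M) %*% b))
    names(theta) <- struct$par_names
    # Residual sums of squares at the new means (exact, from the E-step
    # sufficient statistics: sum_c sum_i r_ic (x_i - mu_c)^2)
    SS <- vapply(GENERATIONS, function(g) {
      pr <- prep[[g]]
      a <- agg[[g]]
      mu <- as.numeric(pr$design %*% theta)
      sum(pr$x^2) - 2 * sum(mu * a$S_c) + sum(mu^2 * a$n_c)
    }, numeric(1))
    ng <- vapply(prep, function(pr) length(pr$x), numeric(1))
    # CM-step 2: variances
    if (!has_pg || !is.null(fix_pg)) {
      if (!is.null(fix_pg) && fix_pg > 0) {
        # sigma2_e with segregating variances offset by the fixed pg value
        s2e <- .update_s2e(SS, ng, prep, pg, var_floor, s2e)
      } else {
        s2e <- max(sum(SS) / sum(ng), var_floor)
      }
    } else {
      seg <- vapply(prep, `[[`, logical(1), "seg")
      pg[SEG_GENERATIONS] <- pmax(0, SS[SEG_GENERATIONS] /
                                     ng[SEG_GENERATIONS] - s2e)
      s2e <- .update_s2e(SS, ng, prep, pg, var_floor, s2e)
      pg[SEG_GENERATIONS] <- pmax(0, SS[SEG_GENERATIONS] /
                                     ng[SEG_GENERATIONS] - s2e)
    }
  }
}

# Conditional maximization for sigma2_e given the per-generation polygenic
# variances: one-dimensional maximization of the expected complete-data
# log-likelihood by safeguarded Newton from the incumbent; falls back to the
# incumbent value if no improvement (preserving EM monotonicity).
.update_s2e <- function(SS, ng, prep, pg, var_floor, incumbent) {
  seg <- which(vapply(prep, `[[`, logical(1), "seg"))
  pgv <- unname(pg[names(prep)[seg]])
  offs <- numeric(length(SS))
  offs[seg] <- pgv
  qfun <- function(s2e) {
    v <- pmax(s2e + offs, var_floor)
    -0.5 * sum(ng * log(v) + SS / v)
  }
  s <- max(incumbent, var_floor)
  for (it in 1:8) {
    v <- pmax(s + offs, var_floor)
    g1 <- -0.5 * sum(ng / v - SS / v^2)          # dQ/ds2e
    g2 <- -0.5 * sum(-ng / v^2 + 2 * SS / v^3)   # d2Q/ds2e2
    if (!is.finite(g1) || !is.finite(g2) || g2 >= 0) break
    step <- g1 / g2
    s_new <- s - step
    if (s_new <= var_floor) s_new <- (s + var_floor) / 2
    if (abs(s_new - s) < 1e-12 * (1 + s)) { s <- s_new; break }
    s <- s_new
  }
  if (qfun(s) >= qfun(incumbent)) s else max(incumbent, var_floor)
}

#' Fit one genetic model to a six-generation dataset
#'
#' Joint maximum likelihood by EM with conditional maximization: the E-step
#' computes component responsibilities within each generation; the first
#' CM-step updates the free mean-parameter vector by responsibility-weighted
#' least squares against the stacked design matrices; the second CM-step
#' updates `sigma2_e` (pooled across all generations) and the per-generation
#' polygenic variances (excess within-component variance of each segregating
#' generation over `sigma2_e`, floored at 0). Multiple seeded starts guard
#' against local optima; the monotonicity of the likelihood is checked every
#' iteration.
#'
#' @param dataset A [six_gen_dataset()].
#' @param model Model code (see [model_registry()]) or a
#'   [build_structure()] object.
#' @param config A [fit_config()].
#' @return Object of class `segfit`: estimates (`theta`, expanded
#'   `params`), realized per-generation component tables, `loglik`, `aic`,
#'   `k`, convergence metadata and posterior responsibilities.
#' @examples
#' cfg <- sim_config("1MG-A", effect_params(m = 100, da = 20, sigma2_e = 25),
#'                   n = c(P1 = 50, P2 = 50, F1 = 50, F2 = 100,
#'                         BC1P1 = 60, BC1P2 = 60), seed = 7)
#' fit <- fit_model(simulate_cross(cfg), "1MG-A", fit_config(n_starts = 3))
#' fit$theta
#' @export
fit_model <- function(dataset, model, config = fit_config()) {
  struct <- if (is.character(model)) build_structure(model) else model
  stopifnot(inherits(dataset, "six_gen_dataset"),
            inherits(struct, "mixture_structure"),
            inherits(config, "fit_config"))
  prep <- lapply(stats::setNames(GENERATIONS, GENERATIONS), function(g) {
    gg <- struct$generations[[g]]
    list(x = dataset$samples[[g]]$values, design = gg$design,
         weights = gg$weights, seg = gg$var_class == "seg")
  })
  allx <- unlist(lapply(prep, `[[`, "x"))
  var_floor <- 1e-6 * stats::var(allx)
  start0 <- .init_start(prep, struct)
  scale <- stats::sd(allx)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  starts <- c(list(start0),
              lapply(seq_len(config$n_starts - 1),
                     function(j) .jitter_start(start0, scale)))
  runs <- suppressWarnings(lapply(starts, function(s) {
    .em_run(prep, struct, s, config$tol, config$max_iter, var_floor,
            fix_pg = config$fix_pg_variance)
  }))
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best_ll <- max(lls)
  cand <- which(lls >= best_ll - 1e-9 * (1 + abs(best_ll)))
  if (length(cand) > 1L) {
    # deterministic tie-break: lexicographically smallest |theta|
    ord <- do.call(order, as.data.frame(t(vapply(runs[cand], function(r)
      abs(r$theta), numeric(length(struct$par_names))))))
    best <- runs[[cand[ord[1]]]]
  } else {
    best <- runs[[cand]]
  }

  pg <- best$pg
  if (struct$polygene == "none" && is.null(config$fix_pg_variance)) pg[] <- 0
  theta <- .canonicalize_loci(struct, best$theta)
  params <- effect_params(theta_to_params(struct, theta),
                          sigma2_e = best$s2e, sigma2_pg = pg)
  comps <- realize_components(struct, theta, best$s2e, pg)
  multi <- vapply(comps, function(cm) length(cm$weights) > 1, logical(1))
  resp <- lapply(stats::setNames(GENERATIONS[multi], GENERATIONS[multi]),
                 function(g) {
    cm <- comps[[g]]
    .gen_estep(prep[[g]]$x, cm$weights, cm$means, cm$variance)$resp
  })
  structure(list(
    model = struct$model, structure = struct,
    theta = theta, params = params,
    components = comps,
    n_per_generation = vapply(prep, function(pr) length(pr$x), integer(1)),
    loglik = best$loglik, k = struct$k,
    aic = -2 * best$loglik + 2 * struct$k,
    n_iterations = best$iter, converged = best$converged,
    starved = best$starved, loglik_trace = best$trace,
    posterior_responsibilities = resp,
    start_logliks = lls, config = config), class = "segfit")
}

#' @export
print.segfit <- function(x, ...) {
  cat("Joint segregation fit:", x$model, "\n")
  cat(sprintf("  logLik = %.4f, k = %d, AIC = %.4f (%s, %d iterations)\n",
              x$loglik, x$k, x$aic,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  est <- c(x$theta, sigma2_e = x$params$sigma2_e)
  if (x$structure$polygene != "none") {
    est <- c(est, stats::setNames(x$params$sigma2_pg,
                                  paste0("sigma2_pg.", names(x$params$sigma2_pg))))
  }
  print(round(est, 4))
  invisible(x)
}

#' Fit a set of genetic models and rank them by AIC
#'
#' @param dataset A [six_gen_dataset()].
#' @param models Character vector of model codes (default: all 24).
#' @param config A [fit_config()] shared by every fit.
#' @return List with `fits` (named list of `segfit`) and `table` (data frame
#'   `model`, `loglik`, `k`, `aic`, `converged`, sorted by AIC).
#' @export
fit_models <- function(dataset, models = model_registry()$name,
                       config = fit_config()) {
  fits <- lapply(stats::setNames(models, models), function(mn) {
    fit_model(dataset, mn, config)
  })
  tab <- data.frame(
    model = models,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
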