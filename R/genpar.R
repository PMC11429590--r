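# Translation of a joint segregation fit into the reported genetic
# parameters: first-order effects on the mean scale (m, d_a, d_b, [d], [h],
# dominance degree [h]/[d], plus dominance/epistatic terms when the model
# frees them) and second-order variance components and heritabilities per
# segregating generation.

#' First-order genetic parameters of a fitted model
#'
#' Recovers the free effect parameters by generalized least squares of the
#' realized component means on the stacked design matrices, weighted by the
#' effective component sample sizes (summed posterior responsibilities) over
#' the component variances. Because the EM already parameterizes the
#' component means by the effect vector, this is the identity map up to
#' numerical error — both routes must agree, which is asserted by the test
#' suite.
#'
#' @param fit A converged [fit_model()] result.
#' @return List of class `first_order_params`: `effects` (named vector of
#'   the model's free mean parameters), `dominance_degree`
#'   (`[h]/[d]`, `NA` when the model has no polygene or `[d] = 0`), and
#'   `gls_effects` (the explicit least-squares recovery).
#' @export
first_order <- function(fit) {
  stopifnot(inherits(fit, "segfit"))
  if (!fit$converged) {
    warning("fit did not converge; first-order parameters may be unreliable")
  }
  struct <- fit$structure
  p <- length(struct$par_names)
  M <- matrix(0, p, p)
  b <- numeric(p)
  for (g in GENERATIONS) {
    gg <- struct$generations[[g]]
    cm <- fit$components[[g]]
    resp <- fit$posterior_responsibilities[[g]]
    n_c <- if (!is.null(resp)) colSums(resp) else fit$n_per_generation[[g]]
    w <- n_c / cm$variance
    M <- M + crossprod(gg$design, w * gg$design)
    b <- b + as.numeric(crossprod(gg$design, w * cm$means))
  }
  qrM <- qr(M)
  if (qrM$rank < p) {
    confounded <- struct$par_names[qrM$pivot[(qrM$rank + 1):p]]
    stop("rank-deficient design under model ", fit$model,
         ": confounded parameter(s) ", paste(confounded, collapse = ", "),
         call. = FALSE)
  }
  gls <- stats::setNames(as.numeric(solve(M, b)), struct$par_names)
  pd <- fit$params$mean["pd"]
  ph <- fit$params$mean["ph"]
  dd <- if (struct$polygene != "none" && pd != 0) unname(ph / pd) else NA_real_
  structure(list(model = fit$model, effects = fit$theta,
                 dominance_degree = dd, gls_effects = gls),
            class = "first_order_params")
}

#' @export
print.first_order_params <- function(x, ...) {
  cat("First-order genetic parameters (", x$model, ")\n", sep = "")
  print(round(x$effects, 4))
  if (!is.na(x$dominance_degree)) {
    cat(sprintf("  dominance degree [h]/[d] = %.4f\n", x$dominance_degree))
  }
  invisible(x)
}

#' Dominance degree of the polygenes
#'
#' `[h]/[d]`: the ratio of the collective dominance to the collective
#' additive polygene effect.
#'
#' @param poly_d,poly_h The collective additive and dominance effects;
#'   `poly_d` must be non-zero.
#' @return Dimensionless ratio.
#' @examples
#' dominance_degree(15.95, 3.20)
#' @export
dominance_degree <- function(poly_d, poly_h) {
  if (any(poly_d == 0)) stop("[d] = 0: dominance degree undefined",
                             call. = FALSE)
  poly_h / poly_d
}

#' Variance decomposition of one segregating generation
#'
#' Applies the additive decomposition `sigma2_p = sigma2_e + sigma2_mg +
#' sigma2_pg`: the major-gene variance is obtained by subtraction (floored
#' at 0 with a warning if negative before flooring) and the heritabilities
#' are the percentage shares of the phenotypic variance.
#'
#' @param sigma2_p Phenotypic variance of the generation (> 0).
#' @param sigma2_e Environmental variance.
#' @param sigma2_pg Polygenic variance.
#' @return One-row data frame: `sigma2_p`, `sigma2_e`, `sigma2_mg`,
#'   `sigma2_pg`, `h2_mg`, `h2_pg`, `h2_total`, `env_fraction`
#'   (percentages).
#' @examples
#' variance_components(410.95, 71.93, 0)      # h2_mg = 82.50
#' variance_components(536.94, 71.93, 239.25) # h2_total = 86.60
#' @export
variance_components <- function(sigma2_p, sigma2_e, sigma2_pg) {
  if (sigma2_p <= 0) stop("sigma2_p must be > 0: heritability undefined",
                          call. = FALSE)
  s2mg <- sigma2_p - sigma2_e - sigma2_pg
  if (s2mg < 0) {
    warning("negative major-gene variance (", format(s2mg),
            ") floored at 0")
    s2mg <- 0
  }
  h2mg <- 100 * s2mg / sigma2_p
  h2pg <- 100 * sigma2_pg / sigma2_p
  data.frame(sigma2_p = sigma2_p, sigma2_e = sigma2_e, sigma2_mg = s2mg,
             sigma2_pg = sigma2_pg,
             h2_mg = h2mg, h2_pg = h2pg, h2_total = h2mg + h2pg,
             env_fraction = 100 * sigma2_e / sigma2_p)
}

#' Second-order genetic parameters of a fitted model
#'
#' For each segregating generation (BC1P1, BC1P2, F2): the sample phenotypic
#' variance (n-1 denominator), the fitted environmental variance, the fitted
#' polygenic variance (within-component variance in excess of `sigma2_e`,
#' floored at 0), the major-gene variance by subtraction, and the
#' corresponding heritability percentages.
#'
#' @param fit A converged [fit_model()] result.
#' @param dataset The [six_gen_dataset()] the model was fitted to.
#' @return Data frame with one row per segregating generation (`generation`
#'   column first), columns as in [variance_components()].
#' @export
second_order <- function(fit, dataset) {
  stopifnot(inherits(fit, "segfit"), inherits(dataset, "six_gen_dataset"))
  if (!fit$converged) {
    warning("fit did not converge; second-order parameters may be unreliable")
  }
  gens <- c("BC1P1", "BC1P2", "F2")
  out <- do.call(rbind, lapply(gens, function(g) {
    s2p <- stats::var(dataset$samples[[g]]$values)
    s2pg <- max(0, fit$components[[g]]$variance - fit$params$sigma2_e)
    cbind(generation = g,
          variance_components(s2p, fit$params$sigma2_e, s2pg),
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
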