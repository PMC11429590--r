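# Registry of the 24 genetic models used in joint segregation analysis of a
# six-generation cross (P1, P2, F1, F2, BC1P1, BC1P2).
#
# Every model is generated from one rule rather than hand-written tables:
#   1. enumerate major-locus genotype classes per generation with Mendelian
#      frequencies (F2 per locus 1:2:1; BC1P1 per locus 1 AA : 1 Aa; BC1P2
#      per locus 1 Aa : 1 aa; parents and F1 are fixed genotypes);
#   2. the genotypic value of a class is a linear combination of the effect
#      parameters, restricted by the model's constraint set;
#   3. the polygene part shifts each generation mean by the classical
#      generation-mean coefficients and adds a per-generation variance
#      sigma2_pg(g) to the segregating generations F2, BC1P1, BC1P2.
# Components whose means coincide under the constraints are merged with their
# Mendelian weights summed; all weight arithmetic is exact (integer numerators
# over a common denominator), and mean coefficients are exact integers on a
# x4 scale so merging never depends on floating point.

GENERATIONS <- c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2")
SEG_GENERATIONS <- c("F2", "BC1P1", "BC1P2")

# Full mean-effect basis: overall mean, additive/dominance of the two major
# genes, digenic epistasis (aa, ad, da, dd), and collective polygene terms
# [d], [h] plus collective epistatic terms [i], [j], [l].
EFFECT_BASIS <- c("m", "da", "ha", "db", "hb", "i", "jab", "jba", "l",
                  "pd", "ph", "pi", "pj", "pl")

# Polygene generation-mean coefficients (pd, ph, pi, pj, pl) on a x4 integer
# scale, i.e. row/4 gives (alpha, beta, alpha^2, alpha*beta, beta^2) with
# (alpha, beta) = (1,0), (-1,0), (0,1), (0,1/2), (1/2,1/2), (-1/2,1/2).
.POLY_COEF4 <- matrix(
  c( 4, 0, 4, 0, 0,
    -4, 0, 4, 0, 0,
     0, 4, 0, 0, 4,
     0, 2, 0, 0, 1,
     2, 2, 1, 1, 1,
    -2, 2, 1, -1, 1),
  nrow = 6, byrow = TRUE,
  dimnames = list(GENERATIONS, c("pd", "ph", "pi", "pj", "pl")))

# Per-locus genotype distributions: additive score u (AA=1, Aa=0, aa=-1),
# dominance score w (Aa=1 else 0), integer weight num over den.
.locus_dist <- function(generation) {
  switch(generation,
    P1    = list(u = 1L,             w = 0L,             num = 1L, den = 1L),
    P2    = list(u = -1L,            w = 0L,             num = 1L, den = 1L),
    F1    = list(u = 0L,             w = 1L,             num = 1L, den = 1L),
    F2    = list(u = c(1L, 0L, -1L), w = c(0L, 1L, 0L),  num = c(1L, 2L, 1L), den = 4L),
    BC1P1 = list(u = c(1L, 0L),      w = c(0L, 1L),      num = c(1L, 1L),     den = 2L),
    BC1P2 = list(u = c(0L, -1L),     w = c(1L, 0L),      num = c(1L, 1L),     den = 2L),
    stop("unknown generation: ", generation))
}

.MODEL_TABLE <- data.frame(
  name = c("1MG-AD", "1MG-A", "1MG-EAD", "1MG-NCD",
           "2MG-ADI", "2MG-AD", "2MG-A", "2MG-EA", "2MG-CD", "2MG-EAD",
           "PG-ADI", "PG-AD",
           "MX1-AD-ADI", "MX1-AD-AD", "MX1-A-AD", "MX1-EAD-AD", "MX1-NCD-AD",
           "MX2-ADI-ADI", "MX2-ADI-AD", "MX2-AD-AD", "MX2-A-AD", "MX2-EA-AD",
           "MX2-CD-AD", "MX2-EAD-AD"),
  loci = c(1L, 1L, 1L, 1L,
           2L, 2L, 2L, 2L, 2L, 2L,
           0L, 0L,
           1L, 1L, 1L, 1L, 1L,
           2L, 2L, 2L, 2L, 2L, 2L, 2L),
  major = c("AD", "A", "EAD", "NCD",
            "ADI", "AD", "A", "EA", "CD", "EAD",
            "none", "none",
            "AD", "AD", "A", "EAD", "NCD",
            "ADI", "ADI", "AD", "A", "EA", "CD", "EAD"),
  polygene = c("none", "none", "none", "none",
               "none", "none", "none", "none", "none", "none",
               "ADI", "AD",
               "ADI", "AD", "AD", "AD", "AD",
               "ADI", "AD", "AD", "AD", "AD", "AD", "AD"),
  stringsAsFactors = FALSE)

#' Registry of the 24 genetic models
#'
#' One row per model: the model code (naming grammar
#' `[major part]-[major constraint][-polygene constraint]`), the number of
#' segregating major loci, the constraint set on major-gene effects, the
#' polygene structure, the number of free mean parameters and the total free
#' parameter count `k` that enters `AIC = -2 lnL + 2k`.
#'
#' Constraint semantics: `A` additive only (dominance and epistasis zero);
#' `AD` additive plus dominance (epistasis zero); `ADI` additive, dominance
#' and digenic epistasis all free; `EA` equal additive effects
#' (`d_a = d_b`, dominance zero); `EAD` one common additive-dominance effect
#' value (`d_a = d_b = h_a = h_b`; for a single gene `h_a = d_a`); `CD`
#' complete dominance (`h = d` per gene); `NCD` negative complete dominance
#' (`h = -d` per gene). Polygene `AD` frees the collective effects `[d]` and
#' `[h]`; polygene `ADI` additionally frees the collective epistatic terms
#' `[i]`, `[j]`, `[l]`. Polygene models carry one free variance
#' `sigma2_pg(g)` per segregating generation on top of `sigma2_e`.
#'
#' @return A data frame with columns `name`, `loci`, `major`, `polygene`,
#'   `n_mean_params`, `k`.
#' @examples
#' model_registry()
#' @export
model_registry <- function() {
  tab <- .MODEL_TABLE
  tab$n_mean_params <- vapply(tab$name, function(nm) {
    length(.constraint_map(nm)$free)
  }, integer(1))
  tab$k <- vapply(tab$name, count_free_parameters, integer(1))
  rownames(tab) <- NULL
  tab
}

.model_row <- function(name) {
  idx <- match(name, .MODEL_TABLE$name)
  if (is.na(idx)) {
    stop("unknown model '", name, "'; valid codes are: ",
         paste(.MODEL_TABLE$name, collapse = ", "), call. = FALSE)
  }
  .MODEL_TABLE[idx, ]
}

# Constraint mapping: C is a (14 x p) integer matrix expressing the full
# effect basis as a linear image of the free parameter vector theta, whose
# entries are named after representative basis symbols.
.constraint_map <- function(name) {
  row <- .model_row(name)
  C <- matrix(0L, nrow = length(EFFECT_BASIS), ncol = 0,
              dimnames = list(EFFECT_BASIS, NULL))
  add_col <- function(C, free_name, loadings) {
    col <- integer(length(EFFECT_BASIS))
    names(col) <- EFFECT_BASIS
    col[names(loadings)] <- loadings
    C <- cbind(C, col)
    colnames(C)[ncol(C)] <- free_name
    C
  }
  C <- add_col(C, "m", c(m = 1L))
  if (row$loci == 1L) {
    C <- switch(row$major,
      A   = add_col(C, "da", c(da = 1L)),
      AD  = add_col(add_col(C, "da", c(da = 1L)), "ha", c(ha = 1L)),
      EAD = add_col(C, "da", c(da = 1L, ha = 1L)),
      NCD = add_col(C, "da", c(da = 1L, ha = -1L)),
      stop("unsupported single-gene constraint: ", row$major))
  } else if (row$loci == 2L) {
    C <- switch(row$major,
      A   = add_col(add_col(C, "da", c(da = 1L)), "db", c(db = 1L)),
      AD  = {
        C <- add_col(C, "da", c(da = 1L)); C <- add_col(C, "ha", c(ha = 1L))
        C <- add_col(C, "db", c(db = 1L)); add_col(C, "hb", c(hb = 1L))
      },
      ADI = {
        for (p in c("da", "ha", "db", "hb", "i", "jab", "jba", "l")) {
          C <- add_col(C, p, stats::setNames(1L, p))
        }
        C
      },
      EA  = add_col(C, "da", c(da = 1L, db = 1L)),
      EAD = add_col(C, "da", c(da = 1L, ha = 1L, db = 1L, hb = 1L)),
      CD  = add_col(add_col(C, "da", c(da = 1L, ha = 1L)),
                    "db", c(db = 1L, hb = 1L)),
      stop("unsupported two-gene constraint: ", row$major))
  }
  if (row$polygene == "AD") {
    C <- add_col(C, "pd", c(pd = 1L))
    C <- add_col(C, "ph", c(ph = 1L))
  } else if (row$polygene == "ADI") {
    for (p in c("pd", "ph", "pi", "pj", "pl")) {
      C <- add_col(C, p, stats::setNames(1L, p))
    }
  }
  list(free = colnames(C), C = C)
}

#' Number of free parameters of a genetic model
#'
#' Counts the free mean parameters remaining after the model's constraint
#' set, plus the free variance parameters: `sigma2_e` always, and one
#' polygenic variance per segregating generation (F2, BC1P1, BC1P2) for
#' models with a polygene component.
#'
#' @param name Model code, e.g. `"MX2-A-AD"`.
#' @return Integer `k` entering `AIC = -2 lnL + 2k`.
#' @examples
#' count_free_parameters("1MG-A")     # m, d_a, sigma2_e
#' count_free_parameters("MX2-A-AD")
#' @export
count_free_parameters <- function(name) {
  row <- .model_row(name)
  p_mean <- length(.constraint_map(name)$free)
  p_var <- 1L + if (row$polygene != "none") 3L else 0L
  p_mean + p_var
}

# Raw x4-scaled coefficient rows over the full effect basis for one
# generation with `loci` segregating major genes. Returns list(coef4, num, den).
.enumerate_classes <- function(generation, loci) {
  poly <- .POLY_COEF4[generation, ]
  base_row <- integer(length(EFFECT_BASIS))
  names(base_row) <- EFFECT_BASIS
  base_row["m"] <- 4L
  base_row[names(poly)] <- as.integer(poly)

  if (loci == 0L) {
    return(list(coef4 = matrix(base_row, nrow = 1,
                               dimnames = list(NULL, EFFECT_BASIS)),
                num = 1L, den = 1L))
  }
  da <- .locus_dist(generation)
  if (loci == 1L) {
    grid <- data.frame(ua = da$u, wa = da$w, ub = 0L, wb = 0L,
                       num = da$num)
    den <- da$den
  } else {
    ia <- seq_along(da$u)
    g <- expand.grid(a = ia, b = ia)
    grid <- data.frame(ua = da$u[g$a], wa = da$w[g$a],
                       ub = da$u[g$b], wb = da$w[g$b],
                       num = da$num[g$a] * da$num[g$b])
    den <- da$den^2
  }
  coef4 <- t(vapply(seq_len(nrow(grid)), function(r) {
    rw <- base_row
    rw["da"] <- 4L * grid$ua[r]; rw["ha"] <- 4L * grid$wa[r]
    rw["db"] <- 4L * grid$ub[r]; rw["hb"] <- 4L * grid$wb[r]
    rw["i"]   <- 4L * grid$ua[r] * grid$ub[r]
    rw["jab"] <- 4L * grid$ua[r] * grid$wb[r]
    rw["jba"] <- 4L * grid$wa[r] * grid$ub[r]
    rw["l"]   <- 4L * grid$wa[r] * grid$wb[r]
    rw
  }, integer(length(EFFECT_BASIS))))
  colnames(coef4) <- EFFECT_BASIS
  list(coef4 = coef4, num = as.integer(grid$num), den = as.integer(den))
}

#' Build the mixture structure of a genetic model
#'
#' Constructs, for each of the six generations, the normal-mixture skeleton
#' implied by the model: exact Mendelian component weights, the integer
#' design matrix mapping the free effect-parameter vector to component means,
#' and the variance rule (`"env"`: `sigma2_e`; `"seg"`: `sigma2_e +
#' sigma2_pg(g)`). Components with identical mean coefficients under the
#' model's constraints are merged and their weights summed; merging compares
#' exact integers, never floating point.
#'
#' @param name Model code from [model_registry()].
#' @return An object of class `mixture_structure`: a list with elements
#'   `model`, `loci`, `major`, `polygene`, `par_names` (free mean
#'   parameters, `m` first), `k`, and `generations` — a named list with, per
#'   generation, `weights` (numeric, sums to 1), `weight_num`/`weight_den`
#'   (exact), `design` (components x parameters, mean coefficients),
#'   `design4` (the same on the exact x4 integer scale) and `var_class`.
#' @examples
#' s <- build_structure("MX2-A-AD")
#' s$generations$F2$weights   # (1,2,1,2,4,2,1,2,1)/16
#' @export
build_structure <- function(name) {
  row <- .model_row(name)
  map <- .constraint_map(name)
  gens <- lapply(GENERATIONS, function(g) {
    cls <- .enumerate_classes(g, row$loci)
    red4 <- cls$coef4 %*% map$C   # integer x4-scale reduced design
    key <- apply(red4, 1, paste, collapse = ",")
    keep <- !duplicated(key)
    num <- as.integer(tapply(cls$num, key, sum)[key[keep]])
    red4 <- red4[keep, , drop = FALSE]
    storage.mode(red4) <- "integer"
    var_class <- if (g %in% SEG_GENERATIONS && row$polygene != "none")
      "seg" else "env"
    list(weights = num / cls$den,
         weight_num = num, weight_den = cls$den,
         design = red4 / 4, design4 = red4,
         var_class = var_class)
  })
  names(gens) <- GENERATIONS
  structure(
    list(model = row$name, loci = row$loci, major = row$major,
         polygene = row$polygene, par_names = map$free, C = map$C,
         k = count_free_parameters(name), generations = gens),
    class = "mixture_structure")
}

#' @export
print.mixture_structure <- function(x, ...) {
  cat("Mixture structure for model", x$model, "\n")
  cat("  free mean parameters:", paste(x$par_names, collapse = ", "),
      " (k =", x$k, "including variances)\n")
  for (g in GENERATIONS) {
    gg <- x$generations[[g]]
    cat(sprintf("  %-6s %d component(s), variance %s\n", g,
                nrow(gg$design),
                if (gg$var_class == "seg") "sigma2_e + sigma2_pg" else "sigma2_e"))
  }
  invisible(x)
}

#' Extract the free parameter vector of a model
#'
#' Maps a full effect-parameter vector (named over the 14-element basis) to
#' the model's free parameter vector `theta`, validating that the full
#' vector satisfies the model's constraints (entries not representable as a
#' linear image of `theta` are rejected).
#'
#' @param struct A [build_structure()] object.
#' @param params Named numeric vector over the effect basis (missing names
#'   are treated as 0); typically the `mean` element of [effect_params()].
#' @param tol Constraint-violation tolerance.
#' @return Named free-parameter vector.
#' @export
params_to_theta <- function(struct, params, tol = 1e-8) {
  full <- stats::setNames(numeric(length(EFFECT_BASIS)), EFFECT_BASIS)
  known <- intersect(names(params), EFFECT_BASIS)
  full[known] <- as.numeric(params[known])
  theta <- full[struct$par_names]
  implied <- as.numeric(struct$C %*% theta)
  bad <- abs(full - implied) > tol * (1 + max(abs(full)))
  if (any(bad)) {
    stop("effect parameters violate the constraints of model ", struct$model,
         ": ", paste(EFFECT_BASIS[bad], collapse = ", "), call. = FALSE)
  }
  theta
}

#' Expand a free parameter vector to the full effect basis
#'
#' Inverse companion of [params_to_theta()].
#'
#' @param struct A [build_structure()] object.
#' @param theta Free-parameter vector in `struct$par_names` order.
#' @return Named vector over the 14-element effect basis.
#' @export
theta_to_params <- function(struct, theta) {
  stats::setNames(as.numeric(struct$C %*% theta), EFFECT_BASIS)
}

#' Realized mixture components of a model at given parameters
#'
#' Per-generation component tables (weights, means, shared component
#' variance) for a free-parameter vector and variance parameters.
#' `sigma2_pg` is a named vector over the segregating generations and is
#' ignored for generations whose variance rule is environmental only.
#'
#' @param struct A [build_structure()] object.
#' @param theta Free-parameter vector.
#' @param sigma2_e Environmental variance (> 0).
#' @param sigma2_pg Named polygenic variances (`F2`, `BC1P1`, `BC1P2`).
#' @return Named list over generations: `weights`, `means`, `variance`.
#' @export
realize_components <- function(struct, theta, sigma2_e,
                               sigma2_pg = c(F2 = 0, BC1P1 = 0, BC1P2 = 0)) {
  stopifnot(sigma2_e > 0)
  lapply(stats::setNames(GENERATIONS, GENERATIONS), function(g) {
    gg <- struct$generations[[g]]
    v <- if (gg$var_class == "seg") sigma2_e + unname(sigma2_pg[g]) else sigma2_e
    list(weights = gg$weights,
         means = as.numeric(gg$design %*% theta),
         variance = v)
  })
}

#' Export the model registry as machine-readable JSON
#'
#' Writes every model's constraint sets, parameter count and per-generation
#' exact weight fractions and design-matrix rows, so the structures can be
#' audited outside R.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
registry_to_json <- function(path) {
  out <- lapply(.MODEL_TABLE$name, function(nm) {
    s <- build_structure(nm)
    gens <- lapply(s$generations, function(gg) {
      list(weight_num = gg$weight_num, weight_den = gg$weight_den,
           design = gg$design, var_class = gg$var_class)
    })
    list(model = nm, loci = s$loci, major = s$major, polygene = s$polygene,
         par_names = s$par_names, k = s$k, generations = gens)
  })
  names(out) <- .MODEL_TABLE$name
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
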