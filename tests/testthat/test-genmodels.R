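test_that("registry holds exactly the 24 models with their parameter counts", {
  reg <- model_registry()
  expect_equal(nrow(reg), 24L)
  expect_false(anyDuplicated(reg$name) > 0)
  # free-parameter counts implied by the published likelihood/AIC pairs
  expected_k <- c(
    "1MG-AD" = 4, "1MG-A" = 3, "1MG-EAD" = 3, "1MG-NCD" = 3,
    "2MG-ADI" = 10, "2MG-AD" = 6, "2MG-A" = 4, "2MG-EA" = 3,
    "2MG-CD" = 4, "2MG-EAD" = 3,
    "PG-ADI" = 10, "PG-AD" = 7,
    "MX1-AD-ADI" = 12, "MX1-AD-AD" = 9, "MX1-A-AD" = 8,
    "MX1-EAD-AD" = 8, "MX1-NCD-AD" = 8,
    "MX2-ADI-ADI" = 18, "MX2-ADI-AD" = 15, "MX2-AD-AD" = 11,
    "MX2-A-AD" = 9, "MX2-EA-AD" = 8, "MX2-CD-AD" = 9, "MX2-EAD-AD" = 8)
  got <- vapply(names(expected_k), count_free_parameters, integer(1))
  expect_equal(got, expected_k)
  expect_error(build_structure("MX9-Z"), "unknown model.*valid codes")
})

test_that("MX2-A-AD structures match brute-force genotype enumeration exactly", {
  s <- build_structure("MX2-A-AD")
  th <- c(m = 107.11, da = 22.43, db = -6.34, pd = 19.65, ph = -0.52)
  shifts <- c(F2 = 0.5 * th[["ph"]],
              BC1P1 = 0.5 * (th[["pd"]] + th[["ph"]]),
              BC1P2 = 0.5 * (th[["ph"]] - th[["pd"]]))
  for (g in c("F2", "BC1P1", "BC1P2")) {
    oracle <- brute_force_components(g, th[["m"]], th[["da"]], th[["db"]],
                                     shifts[[g]])
    got_means <- as.numeric(s$generations[[g]]$design %*% th[s$par_names])
    # match component-by-component after sorting by mean
    o <- order(oracle$means); o2 <- order(got_means)
    expect_equal(got_means[o2], oracle$means[o], tolerance = 1e-12)
    expect_equal(s$generations[[g]]$weights[o2], oracle$weights[o])
  }
  expect_equal(s$generations$F2$weight_num, c(1L, 2L, 1L, 2L, 4L, 2L, 1L, 2L, 1L))
  expect_equal(s$generations$F2$weight_den, 16L)
  expect_equal(s$generations$BC1P1$weights, rep(1 / 4, 4))
  # non-segregating generation of a single-gene model
  s1 <- build_structure("1MG-A")
  expect_equal(nrow(s1$generations$P1$design), 1L)
  expect_equal(as.numeric(s1$generations$P1$design %*% c(100, 20)), 120)
})

test_that("weights are exact non-negative rationals summing to 1 in all models", {
  for (nm in model_registry()$name) {
    s <- build_structure(nm)
    for (g in names(s$generations)) {
      gg <- s$generations[[g]]
      expect_true(all(gg$weight_num > 0L))
      expect_identical(sum(gg$weight_num), gg$weight_den)
      expect_equal(sum(gg$weights), 1)
    }
    # parents and F1 are always single-component
    for (g in c("P1", "P2", "F1")) {
      expect_equal(nrow(s$generations[[g]]$design), 1L)
    }
  }
})

test_that("constraint-collapsed models merge components with equal means", {
  # equal additive effects: F2 collapses from 9 to 5 binomial classes
  s <- build_structure("MX2-EA-AD")
  expect_equal(s$generations$F2$weight_num, c(1L, 4L, 6L, 4L, 1L))
  expect_equal(s$generations$F2$weight_den, 16L)
  # one common additive-dominance value d: in BC1P1 both per-locus classes
  # (AA and Aa) contribute +d, so all four classes share the mean m + 2d
  s2 <- build_structure("2MG-EAD")
  expect_equal(nrow(s2$generations$BC1P1$design), 1L)
  # F2 per-locus value is +d with probability 3/4 and -d with 1/4
  expect_equal(s2$generations$F2$weight_num, c(9L, 6L, 1L))
})

test_that("nested models reproduce each other's component means", {
  # 2MG-AD at h_a = h_b = 0 realizes the same components as 2MG-A
  thA <- c(m = 100, da = 15, db = 5)
  sAD <- build_structure("2MG-AD")
  sA <- build_structure("2MG-A")
  pAD <- effect_params(m = 100, da = 15, db = 5, ha = 0, hb = 0, sigma2_e = 10)
  pA <- effect_params(m = 100, da = 15, db = 5, sigma2_e = 10)
  for (g in c("F2", "BC1P1", "BC1P2")) {
    mAD <- sort(as.numeric(sAD$generations[[g]]$design %*%
                             params_to_theta(sAD, pAD$mean)))
    mA <- sort(as.numeric(sA$generations[[g]]$design %*%
                            params_to_theta(sA, pA$mean)))
    expect_equal(unique(round(mAD, 10)), unique(round(mA, 10)))
  }
  # MX2-A-AD with [d] = [h] = 0 collapses to the 2MG-A mean structure
  sMX <- build_structure("MX2-A-AD")
  pMX <- effect_params(m = 100, da = 15, db = 5, sigma2_e = 10)
  for (g in c("F2", "BC1P1", "BC1P2")) {
    mMX <- sort(as.numeric(sMX$generations[[g]]$design %*%
                             params_to_theta(sMX, pMX$mean)))
    mA <- sort(as.numeric(sA$generations[[g]]$design %*% c(100, 15, 5)))
    expect_equal(mMX, mA)
  }
})

test_that("params violating a model's constraints are rejected", {
  s <- build_structure("MX2-A-AD")
  expect_error(params_to_theta(s, effect_params(m = 1, ha = 3)$mean),
               "violate the constraints.*ha")
  # NCD forces h = -d
  sn <- build_structure("1MG-NCD")
  th <- params_to_theta(sn, effect_params(m = 0, da = 7, ha = -7)$mean)
  expect_equal(unname(th["da"]), 7)
  expect_error(params_to_theta(sn, effect_params(m = 0, da = 7, ha = 7)$mean),
               "violate")
})

test_that("registry JSON export is machine-readable and complete", {
  path <- withr::local_tempfile(fileext = ".json")
  registry_to_json(path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(js, 24L)
  expect_equal(js[["MX2-A-AD"]]$k, 9)
  expect_equal(js[["MX2-A-AD"]]$generations$F2$weight_num,
               c(1, 2, 1, 2, 4, 2, 1, 2, 1))
})
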