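test_that("packaged coefficient table loads with the documented totals", {
  vc <- load_coefficients()
  expect_equal(unname(vc$class_totals),
               c(986.69, 225.56, 293.25, 0, 0, 8103.5), tolerance = 1e-9)
  expect_equal(vc$vc["water", "Hr"], 5445)
  expect_equal(vc$vc["water", "WS"], 2117)
  expect_equal(ncol(vc$vc), 17)
  expect_true(all(vc$vc[c("built_up", "barren"), ] == 0))
  expect_setequal(unique(vc$functions$category),
                  c("provisioning", "regulatory", "supporting",
                    "recreation_culture"))
})

test_that("coefficient validation catches total mismatches, zeros warn", {
  src <- system.file("extdata", "value_coefficients.csv",
                     package = "lulcesv")
  tab <- read.csv(src, check.names = FALSE)
  tab$forestland[tab$function_code == "TOTAL"] <- 900
  bad <- tempfile(fileext = ".csv")
  write.csv(tab, bad, row.names = FALSE, na = "")
  expect_error(load_coefficients(bad), "forestland")

  zero <- tab[tab$function_code != "TOTAL", ]
  zero[lulc_legend()$class_name] <- 0
  zf <- tempfile(fileext = ".csv")
  write.csv(zero, zf, row.names = FALSE)
  expect_warning(vz <- load_coefficients(zf), "zero")
  expect_true(all(vz$class_totals == 0))
})

test_that("per-class ESVs reproduce the published figures", {
  vc <- load_coefficients()
  a84 <- study_areas()[["1984"]]
  k84 <- esv_by_class(a84, vc)
  expect_equal(round(k84[["forestland"]] / 1e6, 1), 10.6)
  expect_equal(round(k84[["grassland"]] / 1e6, 1), 7.7)
  a21 <- study_areas()[["2021"]]
  expect_equal(round(esv_by_class(a21, vc)[["water"]] / 1e6, 1),
               7.4)
  expect_equal(esv_by_class(area_table(c(built_up = 5000)), vc)[["built_up"]],
               0)
  expect_error(esv_by_class(a84, vc, extra_esv = c(nonsense = 1)),
               "unknown")
})

test_that("per-function ESVs reproduce the published figures", {
  vc <- load_coefficients()
  f84 <- esv_by_function(study_areas()[["1984"]], vc)
  expect_equal(round(f84[["Hr"]] / 1e6, 1), 37.2)
  expect_equal(round(f84[["WS"]] / 1e6, 1), 14.5)
  expect_equal(f84[["Cu"]], 10706.4 * 2)   # forest-only function
})

test_that("total ESV equals both marginal sums on random inputs", {
  vc <- load_coefficients()
  set.seed(9)
  for (i in 1:20) {
    a <- area_table(setNames(runif(6, 0, 5e4), lulc_legend()$class_name))
    expect_equal(esv_total(a, vc), sum(esv_by_class(a, vc)))
    expect_equal(esv_total(a, vc), sum(esv_by_function(a, vc)))
  }
  one <- area_table(c(forestland = 10))
  vc1 <- vc; vc1$vc[] <- 0; vc1$vc["forestland", "WS"] <- 2
  vc1$class_totals <- rowSums(vc1$vc)
  expect_equal(esv_total(one, vc1), 20)
})

test_that("conservation also holds with random coefficient tables", {
  set.seed(14)
  leg <- lulc_legend()
  for (i in 1:10) {
    vc <- load_coefficients()
    vc$vc[] <- round(runif(length(vc$vc), 0, 500), 2)
    vc$class_totals <- rowSums(vc$vc)
    a <- area_table(setNames(runif(6, 0, 1e4), leg$class_name))
    expect_equal(sum(esv_by_class(a, vc)), sum(esv_by_function(a, vc)))
    # monotonicity: growing one class's area never lowers the total
    a2 <- a; a2$area_ha[3] <- a2$area_ha[3] + 1000
    attr(a2, "total_area_ha") <- sum(a2$area_ha)
    expect_gte(esv_total(a2, vc), esv_total(a, vc))
  }
})

test_that("percent change honours both rounding modes", {
  expect_equal(round(esv_percent_change(55.1e6, 7.4e6), 1), -86.6)
  expect_equal(round(esv_percent_change(10.6e6, 4.9e6), 1), -53.8)
  expect_equal(esv_percent_change(5e6, 5e6), 0)
  # paper mode rounds to 0.1 M first; raw mode does not
  expect_equal(esv_percent_change(10.563888e6, 4.938689e6, "paper"),
               (4.9 - 10.6) / 10.6 * 100)
  expect_equal(esv_percent_change(10.563888e6, 4.938689e6, "raw"),
               (4.938689 - 10.563888) / 10.563888 * 100)
  expect_error(esv_percent_change(0, 5, "raw"), "zero")
  expect_error(esv_percent_change(0.04e6, 5e6, "paper"), "zero")
})

test_that("proportional-perturbation elasticity equals the value share", {
  vc <- load_coefficients()
  a <- study_areas()[["1984"]]
  k <- esv_by_class(a, vc)
  total <- sum(k)
  for (p in c(0.1, 0.5, 0.9, -0.1, -0.5, -0.9)) {
    for (cl in c("forestland", "grassland", "water")) {
      cs <- coefficient_sensitivity(a, vc, cl, p)$cs
      expect_equal(cs, k[[cl]] / total, tolerance = 1e-12)
    }
  }
  # zero-coefficient class: CS = 0; and +/- perturbations agree
  expect_equal(coefficient_sensitivity(a, vc, "barren", 0.5)$cs, 0)
  expect_equal(coefficient_sensitivity(a, vc, "water", 0.5)$cs,
               coefficient_sensitivity(a, vc, "water", -0.5)$cs)
  # shares over all classes (zero-coefficient ones included) sum to 1
  shares <- vapply(rownames(vc$vc), function(cl)
    coefficient_sensitivity(a, vc, cl, 0.5)$cs, 0)
  expect_equal(sum(shares), 1, tolerance = 1e-12)
})

test_that("sensitivity coefficients reproduce the published water values", {
  vc <- load_coefficients()
  cs84 <- coefficient_sensitivity(study_areas()[["1984"]], vc, "water", 0.5,
                                  extra_esv = c(cultivated = 7.4e6))
  expect_equal(round(cs84$cs, 2), 0.68)
  expect_equal(cs84$elasticity, "inelastic")
  cs21 <- coefficient_sensitivity(study_areas()[["2021"]], vc, "water", 0.5,
                                  extra_esv = c(cultivated = 9.6e6))
  expect_equal(round(cs21$cs, 2), 0.28)
  # every class inelastic under this configuration
  for (cl in rownames(vc$vc))
    expect_lt(coefficient_sensitivity(study_areas()[["1984"]], vc, cl, 0.5,
                                      extra_esv = c(cultivated = 7.4e6))$cs,
              1)
})

test_that("esv_report bundles epochs, conserves totals, reports changes", {
  vc <- load_coefficients()
  xtra <- list("1984" = c(cultivated = 7.4e6),
               "1991" = c(cultivated = 7.9e6),
               "2001" = c(cultivated = 7.9e6, water = 9.0e6,
                          grassland = 5.6e6 - 18985.62 * 293.25,
                          forestland = 5.5e6 - 5583.04 * 986.69),
               "2021" = c(cultivated = 9.6e6))
  rep <- esv_report(study_areas(), vc, extra_esv_by_epoch = xtra)
  expect_equal(colSums(rep$by_class), rep$totals)
  expect_equal(colSums(rep$by_function), rep$totals, tolerance = 1e-9)
  tot <- rep$changes[rep$changes$scope == "total" &
                       rep$changes$epoch_a == "1984" &
                       rep$changes$epoch_b == "2021", ]
  expect_equal(round(tot$change_pct, 1), -67.3)
  wat <- rep$changes[rep$changes$scope == "class" &
                       rep$changes$name == "water" &
                       rep$changes$epoch_a == "1984" &
                       rep$changes$epoch_b == "2021", ]
  expect_equal(round(wat$change_pct, 1), -86.6)
  hr <- rep$changes[rep$changes$scope == "function" &
                      rep$changes$name == "Hr" &
                      rep$changes$epoch_a == "1984" &
                      rep$changes$epoch_b == "2021", ]
  expect_equal(round(hr$change_pct, 1), -86.3)
  expect_error(esv_report(study_areas(), vc,
                          epoch_pairs = list(c("1984", "2525"))),
               "undeclared")
})
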