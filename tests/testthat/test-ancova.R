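make_groups <- function(n = 20, intercepts = c(3, 3), slope = -1,
                        sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(intercepts), function(i) {
    x <- runif(n, 0.5, 2)
    data.frame(vpd_kpa = x,
               wue_umol_mmol = intercepts[i] + slope * x + rnorm(n, 0, sd),
               treatment = paste0("g", i))
  }))
}

test_that("a single exact line is recovered with r2 = 1", {
  d <- data.frame(vpd_kpa = seq(0.5, 2, length.out = 10),
                  treatment = "FI")
  d$wue_umol_mmol <- 3 - d$vpd_kpa
  a <- suppressWarnings(wue_vpd_ancova(d))  # lm warns on an exact fit
  expect_equal(a$lines$slope, -1, tolerance = 1e-12)
  expect_equal(a$lines$intercept, 3, tolerance = 1e-12)
  expect_equal(a$lines$r2, 1, tolerance = 1e-12)
})

test_that("identical lines share a letter; separated intercepts do not", {
  same <- wue_vpd_ancova(make_groups(seed = 2))
  expect_true(same$slopes_homogeneous)
  expect_equal(unname(same$letters), c("a", "a"))

  apart <- wue_vpd_ancova(make_groups(intercepts = c(3, 4), seed = 2))
  expect_true(apart$slopes_homogeneous)
  expect_equal(length(unique(apart$letters)), 2L)
})

test_that("heterogeneous slopes suppress the letter display", {
  set.seed(3)
  d1 <- data.frame(vpd_kpa = runif(30, 0.5, 2), treatment = "a")
  d1$wue_umol_mmol <- 3 - 1 * d1$vpd_kpa + rnorm(30, 0, 0.05)
  d2 <- data.frame(vpd_kpa = runif(30, 0.5, 2), treatment = "b")
  d2$wue_umol_mmol <- 1 + 1 * d2$vpd_kpa + rnorm(30, 0, 0.05)
  a <- wue_vpd_ancova(rbind(d1, d2))
  expect_false(a$slopes_homogeneous)
  expect_null(a$letters)
  expect_lt(a$slope_test$p, 0.05)
})

test_that("significance stars mirror the conventional thresholds", {
  expect_equal(ballberry:::p_stars(c(0.2, 0.03, 0.005, 1e-5)),
               c("ns", "*", "**", "***"))
})

test_that("compact letters partition a chain of overlapping groups", {
  # A differs from C; B differs from neither -> A:a, B:ab, C:b
  pm <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pm["A", "C"] <- pm["C", "A"] <- 0.001
  lt <- ballberry:::compact_letters(pm)
  expect_equal(unname(lt), c("a", "ab", "b"))
  # all mutually different -> three distinct letters
  pm[] <- 0.001; diag(pm) <- 1
  expect_equal(length(unique(ballberry:::compact_letters(pm))), 3L)
})

test_that("degenerate designs are refused", {
  d <- make_groups()
  d$vpd_kpa[d$treatment == "g1"] <- 1
  expect_error(wue_vpd_ancova(d), "singular")
  expect_error(wue_vpd_ancova(make_groups(n = 2)), "at least 3")
})
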