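small_surface_setup <- function() {
  pop <- founder_population(20, 20, n_captive_f = 10, n_captive_m = 10)
  params <- test_params(
    p_pair = 0.8,
    mortality = c(pup = 0.3, yearling = 0.2, adult = 0.2),
    litter_dist = c(0.2, 0.2, 0.3, 0.3),
    quasi_threshold = 10
  )
  list(pop = pop, params = params)
}

test_that("a single-cell sweep reproduces run_scenario on the patched parameters", {
  s <- small_surface_setup()
  surf <- sweep_cap_release(s$params, s$pop, cap_values = 60,
                            release_levels = list(none = numeric(0)),
                            n_iter = 8, years = 15, seed = 5)
  expect_equal(nrow(surf$grid), 1)
  p <- s$params
  p$cap <- 60
  p$release_schedule <- numeric(0)
  ref <- run_scenario(p, s$pop, n_iter = 8, years = 15, seed = surf$grid$seed)
  expect_equal(surf$grid$p_ext, ref$p_ext)
  expect_equal(surf$grid$p_quasi, ref$p_quasi)
  expect_equal(surf$grid$mean_GD, ref$mean_GD)
})

test_that("the default grid spans 10 caps by 2 release levels", {
  s <- small_surface_setup()
  surf <- sweep_cap_release(s$params, s$pop, n_iter = 1, years = 2, seed = 1)
  expect_equal(nrow(surf$grid), 20)
  expect_equal(length(unique(surf$grid$cap)), 10)
  expect_setequal(unique(surf$grid$release_level), c("high", "low"))
})

test_that("cell seeds are position-derived, so evaluation order cannot matter", {
  s <- small_surface_setup()
  surf1 <- sweep_cap_release(s$params, s$pop, cap_values = c(40, 80),
                             release_levels = list(a = numeric(0), b = c("1" = 3)),
                             n_iter = 4, years = 10, seed = 9)
  surf2 <- sweep_cap_release(s$params, s$pop, cap_values = c(40, 80),
                             release_levels = list(a = numeric(0), b = c("1" = 3)),
                             n_iter = 4, years = 10, seed = 9)
  expect_identical(surf1$grid, surf2$grid)
  expect_equal(length(unique(surf1$grid$seed)), 4)
})

test_that("retention against a baseline identifies the minimal qualifying cap", {
  # constructed increasing curve crossing 0.9 x baseline between caps 6 and 7
  baseline <- 0.8
  caps <- 1:10
  gd <- baseline * (0.858 + 0.006 * caps)
  surf <- list(grid = data.frame(cap = rep(caps, 2),
                                 release_level = rep(c("high", "low"), each = 10),
                                 p_ext = 0, p_quasi = 0,
                                 mean_GD = rep(gd, 2), n_iter = 10, seed = 1))
  class(surf) <- "pva_surface"
  stopifnot(gd[6] < 0.9 * baseline, gd[7] >= 0.9 * baseline)
  ret <- gd_retention_curve(surf, baseline, target = 0.9)
  expect_equal(ret$minimal_cap$minimal_cap, c(7, 7))
  # retention of a scenario against its own diversity is exactly 1
  self_ret <- gd_retention_curve(surf, gd[4], target = 1)
  expect_equal(self_ret$cells$retained[self_ret$cells$cap == 4][1], 1)
  # a depleted (shifting) baseline can only relax the qualifying cap
  ret_shifted <- gd_retention_curve(surf, baseline * 0.9, target = 0.9)
  expect_true(all(ret_shifted$cells$retained >= ret$cells$retained))
  expect_true(all(is.na(ret_shifted$minimal_cap$minimal_cap) |
                    ret_shifted$minimal_cap$minimal_cap <= ret$minimal_cap$minimal_cap))
  expect_error(gd_retention_curve(surf, 0), "> 0")
})

test_that("captive baselines order as current >= future under continued drift", {
  cp <- make_founder_pedigree(seed = 4)
  pop <- make_initial_population(cp, n = 30, seed = 4)
  # strong-drift regime: small capacity, unmanaged pairing
  params <- pva_params(captive_capacity = c(20L, 30L),
                       pairing_policy = "random")
  cur <- baseline_gd(pop, "current_captive")
  fut <- baseline_gd(pop, "future_captive", params = params, year = 60, seed = 2)
  expect_gt(cur, fut)
  expect_gt(baseline_gd(pop, "founders"), cur)
})

test_that("the threshold survey is summarized by count, range, mode and shares", {
  tab <- make_threshold_table(seed = 1)
  s <- threshold_survey_summary(tab)
  expect_equal(s$count, 60L)
  expect_equal(s$range, c(1, 10))
  expect_equal(s$modal_threshold, 5)
  expect_equal(s$modal_share_pct, 73)
  expect_equal(sum(s$distribution$n), 60L)

  empty <- tab[0, ]
  s0 <- threshold_survey_summary(empty)
  expect_equal(s0$count, 0L)
  expect_equal(nrow(s0$distribution), 0L)

  one <- data.frame(species = "x", threshold_pct = 5, horizon_years = 100)
  s1 <- threshold_survey_summary(one)
  expect_equal(s1$range, c(5, 5))
  expect_equal(s1$modal_threshold, 5)

  messy <- rbind(tab, data.frame(species = "bad", threshold_pct = "n/a",
                                 horizon_years = 100))
  expect_message(sm <- threshold_survey_summary(messy), "rejected")
  expect_equal(sm$count, 60L)
})
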