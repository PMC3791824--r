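tbl_b <- rcdqi_targets("table_b")
tbl_c <- rcdqi_targets("table_c")

test_that("age-indexed target lookup matches the printed table cells", {
  expect_equal(lookup_target("total_grains", 2, tbl_b), 3)
  expect_equal(lookup_target("total_grains", 9, tbl_b), 6)
  expect_equal(lookup_target("total_grains", 14, tbl_b), 7)
  expect_equal(lookup_target("fruit", 2, tbl_b), 1.5)
  expect_equal(lookup_target("fruit", 9, tbl_b), 2)
  expect_equal(lookup_target("vegetable", 3, tbl_b), 1)
  expect_equal(lookup_target("vegetable", 14, tbl_b), 4)
  expect_equal(lookup_target("excess_juice", 6, tbl_b), 6)
  expect_equal(lookup_target("excess_juice", 7, tbl_b), 12)
  expect_equal(lookup_target("dairy", 8, tbl_b), 2)
  expect_equal(lookup_target("dairy", 9, tbl_b), 3)
  expect_equal(lookup_target("eer", 2, tbl_b), 1072)
  expect_equal(lookup_target("eer", 18, tbl_b), 1690)
  # variant c differs where printed
  expect_equal(lookup_target("total_grains", 4, tbl_c), 5)
  expect_equal(lookup_target("whole_grains", 18, tbl_c), 4.5)
  expect_equal(lookup_target("fruit", 13, tbl_c), 2)
  expect_equal(lookup_target("vegetable", 9, tbl_c), 4)
  expect_equal(lookup_target("eer", 2, tbl_c), 1120)
  expect_error(lookup_target("fruit", 1, tbl_b), "between 2 and 18")
  expect_error(lookup_target("nope", 5, tbl_b), "Unknown")
})

test_that("food-group scoring deducts proportionally, zero only at zero", {
  expect_equal(score_food_group(1.5, 1.5, 10), 10)
  expect_equal(score_food_group(0, 1.5, 10), 0)
  expect_equal(score_food_group(0.75, 1.5, 10), 5)
  expect_equal(score_food_group(5, 1.5, 10), 10) # capped at the target
  expect_error(score_food_group(1, 0, 10), "positive")
  expect_error(score_food_group(-1, 1, 10), "non-negative")
  set.seed(41)
  intake <- c(0, runif(200, 1e-9, 10))
  pts <- score_food_group(intake, 3, 10)
  expect_identical(pts == 0, intake == 0)
})

test_that("range scoring is full inside the band and decays outside", {
  expect_equal(score_range(35, 30, 40, 2.5), 2.5)
  expect_equal(score_range(0, 30, 40, 2.5), 0)
  expect_equal(score_range(15, 30, 40, 2.5), 1.25) # below-range branch
  expect_equal(score_range(80, 30, 40, 2.5), 2.5 * 40 / 80)
  expect_error(score_range(1, 40, 30, 2.5), "lo < hi")
  # independent piecewise oracle for the below-range segment
  grid <- seq(0, 30, length.out = 101)
  expect_equal(
    score_range(grid, 30, 40, 2.5),
    prorate_oracle(grid, 0, 30, 2.5),
    tolerance = 1e-12
  )
})

test_that("cap scoring is full at or below the cap and ratio-decays above", {
  expect_equal(score_cap(10, 10, 10), 10)
  expect_equal(score_cap(20, 10, 10), 5)
  expect_equal(score_cap(0, 10, 10), 10) # nothing consumed is within the cap
  expect_equal(score_cap(6, 6, 10), 10) # juice at the age-2 limit
  expect_error(score_cap(1, 0, 10), "positive")
  # brute-force oracle: cap/value decay
  v <- seq(10, 100, by = 0.5)
  expect_equal(score_cap(v, 10, 10), 10 * pmin(1, 10 / v), tolerance = 1e-12)
})

test_that("iron is categorical on the printed age-band thresholds", {
  expect_equal(score_iron(2.0, 3, tbl_b), 0)
  expect_equal(score_iron(5.0, 3, tbl_b), 5)
  expect_equal(score_iron(7.0, 3, tbl_b), 10)
  expect_equal(score_iron(3.0, 2, tbl_b), 0) # at the EAR bound
  expect_equal(score_iron(4.1, 6, tbl_b), 0)
  expect_equal(score_iron(9.9, 6, tbl_b), 5)
  expect_equal(score_iron(10, 6, tbl_b), 10)
  expect_equal(score_iron(5.7, 10, tbl_b), 0)
  expect_equal(score_iron(8, 10, tbl_b), 10)
  expect_equal(score_iron(14.9, 16, tbl_b), 5)
  expect_equal(score_iron(15, 16, tbl_b), 10)
  # variant c upper bands
  expect_equal(score_iron(5.9, 10, tbl_c), 0)
  expect_equal(score_iron(11, 16, tbl_c), 10)
  expect_equal(score_iron(10.9, 16, tbl_c), 5)
  expect_error(score_iron(-1, 5, tbl_b), "non-negative")
})

test_that("TV scoring gives full points up to 2 h and imputes missing hours", {
  expect_equal(score_tv(2, 10), 10)
  expect_equal(score_tv(1, 10), 10)
  expect_equal(score_tv(4, 10), 5) # decay branch: 10 * 2 / 4
  expect_equal(score_tv(NA, 4), 10) # imputed 2 h for ages 2-6
  expect_equal(score_tv(NA, 10), 5) # imputed 4 h for ages 7-14
  expect_equal(score_tv(NA, 16), 10 * 2 / 3.5) # 3.5 h for ages 15-18
  expect_error(score_tv(-1, 5), "non-negative")
})

test_that("energy scoring is full within the EER window, proportional outside", {
  expect_equal(score_energy(1000, 1000), 10)
  expect_equal(score_energy(900, 1000), 10) # lower window edge
  expect_equal(score_energy(1100, 1000), 10) # upper window edge
  expect_equal(score_energy(450, 1000), 5) # half the lower edge
  expect_equal(score_energy(2200, 1000), 5) # twice the upper edge
  expect_equal(score_energy(0, 1000), 0) # zero only at zero intake
  expect_error(score_energy(100, 0), "positive")
  # the literal footnote formula collapses to ~0 just below the window
  # edge (its documented discontinuity); the proportional formula does not
  expect_equal(score_energy(900, 1000, method = "literal"), 10)
  expect_lt(score_energy(899.99, 1000, method = "literal"), 0.001)
  expect_gt(score_energy(899.99, 1000), 9.99)
  expect_equal(score_energy(450, 1000, method = "literal"), 5)
})

test_that("continuous components are continuous at every breakpoint", {
  eps <- 1e-9
  near <- function(x) c(x - eps, x, x + eps)
  # food group at its target
  expect_equal(diff(range(score_food_group(near(1.5), 1.5, 10))), 0,
    tolerance = 1e-6)
  # range edges
  expect_equal(diff(range(score_range(near(30), 30, 40, 2.5))), 0,
    tolerance = 1e-6)
  expect_equal(diff(range(score_range(near(40), 30, 40, 2.5))), 0,
    tolerance = 1e-6)
  # cap
  expect_equal(diff(range(score_cap(near(10), 10, 10))), 0, tolerance = 1e-6)
  # TV threshold
  expect_equal(diff(range(score_tv(near(2), 10))), 0, tolerance = 1e-6)
  # EER window edges under the proportional formula
  expect_equal(diff(range(score_energy(near(900), 1000))), 0, tolerance = 1e-6)
  expect_equal(diff(range(score_energy(near(1100), 1000))), 0, tolerance = 1e-6)
})

test_that("a child meeting every target earns the full 90 points", {
  for (age in c(2, 5, 9, 14, 18)) {
    profile <- make_profile(age = age, tv_hours = 1)
    scores <- score_rcdqi(profile, rcdqi_perfect_usual(age))
    expect_equal(scores$total, 90)
  }
})

test_that("the printed age-9 grain example scores its full 5 points", {
  profile <- make_profile(age = 9)
  usual <- make_usual(total_grains = 6, whole_grains = 1)
  scores <- score_rcdqi(profile, usual)
  expect_equal(scores$total_grains, 5)
})

test_that("zero consumption of the food groups scores zero on each", {
  profile <- make_profile(age = 7, tv_hours = 24)
  usual <- five_group_zero_usual()
  usual$iron <- 2
  scores <- score_rcdqi(profile, usual)
  for (comp in c("total_grains", "whole_grains", "fruit", "vegetable", "dairy")) {
    expect_equal(scores[[comp]], 0)
  }
  expect_equal(scores$iron, 0)
})

test_that("RC-DQI totals stay within [0, 90] on random children", {
  sim <- simulate_children(sim_config(n_children = 300, seed = 43))
  scored <- suppressMessages(
    dqi_score(sim$children, sim$intake)
  )
  expect_true(all(scored$rcdqi$total >= 0 & scored$rcdqi$total <= 90))
  comps <- setdiff(names(scored$rcdqi), c("child_id", "total"))
  expect_equal(
    rowSums(as.matrix(scored$rcdqi[comps])),
    scored$rcdqi$total
  )
})

test_that("table variants differ only where the printed targets differ", {
  sim <- simulate_children(sim_config(n_children = 120, seed = 44))
  usual <- average_intake(sim$intake)
  profiles <- child_profiles(sim$children)
  b <- score_rcdqi(profiles, usual, variant = "table_b")
  c_ <- score_rcdqi(profiles, usual, variant = "table_c")
  # macronutrient rules, juice limits, dairy targets and TV are shared
  for (comp in c(
    "added_sugar", "fat", "linoleic", "linolenic", "dha_epa",
    "excess_juice", "dairy"
  )) {
    expect_equal(b[[comp]], c_[[comp]])
  }
  # grain targets differ from age 4 up, so some scores must move
  ages <- profiles$age[match(b$child_id, profiles$child_id)]
  older <- ages >= 4 & b$total_grains < 5
  expect_true(any(b$total_grains[older] != c_$total_grains[older]))
})

test_that("the five-group zero contract holds over random intakes", {
  set.seed(45)
  tbl <- tbl_b
  for (comp in c("total_grains", "whole_grains", "fruit", "vegetable", "dairy")) {
    ages <- sample(2:18, 50, replace = TRUE)
    intakes <- c(0, runif(49, 1e-6, 8))
    pts <- score_food_group(
      intakes, lookup_target(comp, ages, tbl),
      max_points = 10
    )
    expect_identical(pts == 0, intakes == 0)
  }
})
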