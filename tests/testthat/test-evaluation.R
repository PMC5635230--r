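# independent Clopper-Pearson oracle: bisection on the exact binomial tails
cp_brute <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  tail_ge <- function(p) sum(dbinom(x:n, n, p))
  tail_le <- function(p) sum(dbinom(0:x, n, p))
  bisect <- function(f, target, increasing) {
    lo <- 0; hi <- 1
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bisect(tail_ge, alpha / 2, TRUE)
  upper <- if (x == n) 1 else bisect(tail_le, alpha / 2, FALSE)
  100 * c(lower, upper)
}

test_that("confusion tables are built per stratum with exclusions applied", {
  calls <- data.frame(
    call = c("AF", "NOT_AF", "AF", "NOT_AF", "AF", "UNGRADABLE"),
    is_af = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    age = c(70, 60, 70, 60, 80, 75),
    grade = c("0", "1", "2a", "0", "3", "0")
  )
  tabs <- build_confusion(calls, exclude_grades = "3")
  expect_identical(tabs$overall$tp, 1L)  # grade-3 AF call excluded
  expect_identical(tabs$overall$fn, 1L)
  expect_identical(tabs$overall$fp, 1L)
  expect_identical(tabs$overall$tn, 1L)
  expect_identical(tabs$le$total, 2L)
  expect_identical(tabs$gt$total, 2L)
  # empty input gives an all-zero table
  empty <- build_confusion(calls[0, ])
  expect_identical(empty$overall$total, 0L)
  # a perfect oracle classifier yields no errors
  oracle <- data.frame(call = ifelse(c(TRUE, FALSE, TRUE), "AF", "NOT_AF"),
                       is_af = c(TRUE, FALSE, TRUE), age = c(50, 70, 80),
                       grade = "0")
  otab <- build_confusion(oracle)
  expect_identical(otab$overall$fp + otab$overall$fn, 0L)
  expect_error(build_confusion(data.frame(call = "AF", is_af = NA, age = 1)),
               class = "afscreen_data_error")
})

test_that("rates reproduce the screening arithmetic, with undefined markers", {
  r <- rates(confusion_table(21, 1, 22, 921))
  expect_equal(round_half_up(r$sensitivity), 95.5)
  expect_equal(round_half_up(r$specificity), 97.7)
  expect_equal(round_half_up(r$ppv), 48.8)
  expect_equal(round_half_up(r$npv), 99.9)
  expect_equal(round_half_up(r$prevalence), 2.3)

  r2 <- rates(confusion_table(0, 0, 0, 10))
  expect_true(is.na(r2$sensitivity))
  expect_equal(r2$specificity, 100)
})

test_that("Clopper-Pearson intervals match the printed study bounds", {
  expect_equal(round_half_up(exact_binomial_ci(21, 22)), c(lower = 77.2, upper = 99.9))
  expect_equal(round_half_up(exact_binomial_ci(4, 4)), c(lower = 39.8, upper = 100.0))
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 100)
  expect_error(exact_binomial_ci(5, 4), class = "afscreen_invalid_parameter")
})

test_that("Clopper-Pearson agrees with the brute-force tail search (spot checks)", {
  for (case in list(c(0, 7), c(3, 9), c(21, 22), c(13, 27))) {
    expect_equal(unname(exact_binomial_ci(case[1], case[2])),
                 cp_brute(case[1], case[2]), tolerance = 1e-6)
  }
})

test_that("the exact interval covers the true proportion at its nominal rate", {
  set.seed(90)
  draws <- rbinom(2000, 22, 0.9)
  covered <- vapply(draws, function(x) {
    ci <- exact_binomial_ci(x, 22)
    ci[1] <= 90 && 90 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("predictive-value logit intervals reproduce the printed bounds", {
  overall <- confusion_table(21, 1, 22, 921)
  expect_equal(round_half_up(predictive_value_ci(overall, "ppv")),
               c(lower = 38.5, upper = 59.3))
  expect_equal(round_half_up(predictive_value_ci(overall, "npv")),
               c(lower = 99.3, upper = 100.0))
  gt65 <- confusion_table(17, 1, 15, 406)
  expect_equal(round_half_up(predictive_value_ci(gt65, "ppv")),
               c(lower = 40.5, upper = 65.4))
  expect_equal(round_half_up(predictive_value_ci(gt65, "npv")),
               c(lower = 98.4, upper = 100.0))
  # perfect sensitivity leaves the NPV without a defined interval
  le65 <- confusion_table(4, 0, 7, 515)
  expect_equal(round_half_up(predictive_value_ci(le65, "ppv")),
               c(lower = 21.5, upper = 54.4))
  expect_true(all(is.na(predictive_value_ci(le65, "npv"))))
})

test_that("PPV is Bayes-consistent with sensitivity, specificity and prevalence", {
  for (t in list(confusion_table(21, 1, 22, 921), confusion_table(4, 0, 7, 515),
                 confusion_table(17, 1, 15, 406))) {
    r <- rates(t)
    se <- r$sensitivity / 100; sp <- r$specificity / 100
    prev <- r$prevalence / 100
    ppv_bayes <- 100 * se * prev / (se * prev + (1 - sp) * (1 - prev))
    expect_equal(ppv_bayes, r$ppv, tolerance = 1e-9)
  }
})

test_that("study reconstruction recovers stratum tables that sum to the overall", {
  sc <- study_confusion_tables()
  expect_identical(sc$tables$le$fp + sc$tables$gt$fp, 22L)
  for (cell in c("tp", "fn", "fp", "tn")) {
    expect_identical(sc$tables$le[[cell]] + sc$tables$gt[[cell]],
                     sc$tables$overall[[cell]])
  }
  expect_identical(sc$tables$overall$total, 965L)
})

test_that("the rendered table formats rates, intervals and prevalences", {
  rec <- reconstruct_table1()
  tab <- rec$table
  expect_identical(tab$overall[1], "95.5 (95% CI 77.2%-99.9%)")
  expect_identical(tab$overall[2], "97.7 (95% CI 96.5%-98.5%)")
  expect_identical(tab$overall[3], "48.8 (95% CI 38.5%-59.3%)")
  expect_identical(tab$overall[4], "99.9 (95% CI 99.3%-100.0%)")
  expect_identical(tab$overall[5], "2.3 (22/965)")
  expect_identical(tab$overall[6], "2.4 (22/922)")
  expect_identical(tab$age_le65[4], "100.0")  # no defined interval at fn = 0
  # degenerate all-zero stratum renders as missing markers
  zero <- performance_report(confusion_table(0, 0, 0, 0))
  tab0 <- render_table1(list(le = zero, gt = zero, overall = zero))
  expect_true(all(tab0$overall[c(1, 2, 3, 4)] == "--"))
})

test_that("percent rounding is half-up at one decimal", {
  expect_equal(round_half_up(36.35), 36.4)
  expect_equal(round_half_up(99.85), 99.9)
  expect_equal(round_half_up(2.25), 2.3)
  expect_equal(round_half_up(-2.25), -2.3)
})
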