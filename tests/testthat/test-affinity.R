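make_inst <- function(gap, sw_days, los, nv, sw_count) {
  tibble::tibble(patient_id = sprintf("P%d", seq_along(gap)),
                 drug = "olanzapine", init_visit = 1L,
                 switch_count = sw_count, switch_days = sw_days,
                 gap_days = gap, los_days = los, n_visits = nv)
}

random_instances <- function(n, seed) {
  withr::with_seed(seed, {
    nv <- sample(1:3, n, replace = TRUE)
    sw <- sample(0:2, n, replace = TRUE)
    make_inst(
      gap = ifelse(nv == 1, NA_real_, runif(n, 1, 600)),
      sw_days = ifelse(sw == 0, NA_real_, runif(n, 1, 400)),
      los = runif(n, 0.5, 80), nv = nv, sw_count = sw)
  })
}

bounds_as_list <- function(b) {
  g <- function(q) unlist(b[b$quantity == q, c("min", "max")], use.names = FALSE)
  list(gap = g("gap_days"), sw = g("switch_days"),
       los = g("los_days"), nv = g("n_visits"))
}

test_that("normalisation bounds come from the training fold and flag degeneracy", {
  b <- fit_bounds(make_inst(c(100, 300), c(10, 20), c(2, 10), c(2, 3), c(1, 1)))
  expect_equal(b[b$quantity == "los_days", ]$min, 2)
  expect_equal(b[b$quantity == "los_days", ]$max, 10)
  expect_false(b[b$quantity == "los_days", ]$degenerate)
  bd <- fit_bounds(make_inst(c(5, 5), c(NA, NA), c(5, 5), c(2, 2), c(0, 0)))
  expect_true(all(bd$degenerate[bd$quantity != "switch_days"]))
  expect_error(fit_bounds(make_inst(numeric(), numeric(), numeric(),
                                    integer(), integer())),
               class = "srx_empty_training_error")
})

test_that("min-max normalisation clips, inverts and handles degenerate bounds", {
  expect_equal(normalize_minmax(2, 2, 10), 0)
  expect_equal(normalize_minmax(2, 2, 10, invert = TRUE), 1)
  expect_equal(normalize_minmax(10, 2, 10), 1)
  expect_equal(normalize_minmax(10, 2, 10, invert = TRUE), 0)
  expect_equal(normalize_minmax(50, 2, 10), 1)   # beyond training max
  expect_equal(normalize_minmax(-5, 2, 10), 0)
  expect_equal(normalize_minmax(7, 5, 5), 0.5)   # degenerate
})

test_that("base score and penalty follow the equal-weight formulation", {
  expect_equal(base_score(data.frame(t = 1, s = 1, l = 1, v = 1)), 1)
  expect_equal(base_score(data.frame(t = 0, s = 0, l = 0, v = 0)), 0)
  expect_equal(base_score(data.frame(t = 0.4, s = 0.6, l = 0.8, v = 0.2)), 0.5)
  expect_equal(apply_penalty(0.98, 0L), 1)     # bonus clips at 1
  expect_equal(apply_penalty(0.05, 2L), 0)     # penalty clips at 0
  expect_equal(apply_penalty(0.5, 1L), 0.4)
  expect_error(apply_penalty(0.5, 3L), class = "srx_invalid_switch_count_error")
})

test_that("the three weighting schemes match their definitions", {
  sch <- affinity_schemes()
  expect_equal(unname(sch$equal$weights), rep(0.25, 4))
  expect_equal(unname(sch$equal$penalties), c(-0.05, 0.10, 0.20))
  w <- sch$stability_heavy$weights
  expect_true(w[["t"]] == w[["s"]] && w[["t"]] > w[["l"]] && w[["l"]] == w[["v"]])
  wb <- sch$burden_heavy$weights
  expect_true(wb[["l"]] == wb[["v"]] && wb[["l"]] > wb[["t"]])
  expect_equal(unname(sch$burden_heavy$penalties),
               unname(sch$equal$penalties) / 2)
  expect_error(affinity_scheme("bad", c(t = .5, s = .5, l = .5, v = .5),
                               sch$equal$penalties),
               class = "srx_invalid_scheme_error")
})

test_that("composed affinity matches the independent one-line oracle", {
  train <- random_instances(300, seed = 1)
  test <- random_instances(300, seed = 2)
  b <- fit_bounds(train)
  got <- compute_affinity(test, b)
  want <- oracle_affinity(test$gap_days, test$switch_days, test$los_days,
                          test$n_visits, test$switch_count, bounds_as_list(b))
  expect_equal(got$affinity, want, tolerance = 1e-12)
  # equal-weight scheme reproduces the quarter-sum formula exactly
  expect_equal(got$base_b, (got$t + got$s + got$l + got$v) / 4,
               tolerance = 1e-12)
})

test_that("affinity respects clipping, switch ordering and monotonicity", {
  train <- random_instances(400, seed = 3)
  b <- fit_bounds(train)
  inst <- random_instances(400, seed = 4)
  scored <- compute_affinity(inst, b)
  expect_true(all(scored$affinity >= 0 & scored$affinity <= 1))

  # identical components, increasing switch count: pre-clip gaps 0.15 / 0.10
  for (sc in list(c(0L, 1L), c(1L, 2L))) {
    i0 <- inst; i0$switch_count <- sc[1]
    i1 <- inst; i1$switch_count <- sc[2]
    a0 <- compute_affinity(i0, b); a1 <- compute_affinity(i1, b)
    pre0 <- a0$base_b - a0$penalty_P
    pre1 <- a1$base_b - a1$penalty_P
    expect_equal(pre0 - pre1, rep(if (sc[1] == 0) 0.15 else 0.10, nrow(inst)))
    expect_true(all(a0$affinity >= a1$affinity))
  }

  # monotone in each raw quantity (pre-clip, multi-visit/switched rows)
  mv <- inst[inst$n_visits > 1 & inst$switch_count > 0, ]
  bump <- function(d, col, delta) { d[[col]] <- d[[col]] + delta; d }
  pre <- function(d) { a <- compute_affinity(d, b); a$base_b - a$penalty_P }
  expect_true(all(pre(bump(mv, "gap_days", 50)) >= pre(mv)))
  expect_true(all(pre(bump(mv, "switch_days", 50)) >= pre(mv)))
  expect_true(all(pre(bump(mv, "los_days", 10)) <= pre(mv)))
  expect_true(all(pre(bump(mv, "n_visits", 1)) <= pre(mv)))
})

test_that("missing-component policies: best-case imputation vs renormalisation", {
  train <- random_instances(100, seed = 6)
  b <- fit_bounds(train)
  single <- make_inst(NA_real_, NA_real_, 10, 1L, 0L)
  best <- compute_affinity(single, b)
  expect_equal(best$t, 1); expect_equal(best$s, 1)
  ren <- compute_affinity(single, b, missing_policy = "renormalize")
  expect_equal(ren$base_b, (ren$l + ren$v) / 2)
})

test_that("test-fold scoring never updates training bounds", {
  train <- random_instances(50, seed = 7)
  test <- random_instances(50, seed = 8)
  test$los_days <- test$los_days + 500  # far outside training range
  b <- fit_bounds(train, provenance = "train_only")
  before <- as.data.frame(b)
  scored <- compute_affinity(test, b)
  expect_identical(as.data.frame(b), before)
  expect_identical(attr(b, "provenance"), "train_only")
  expect_true(all(scored$l == 0))  # out-of-range clips, never extrapolates
})
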