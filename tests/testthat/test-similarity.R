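test_that("cosine similarity matches its formula and handles zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.70710678,
               tolerance = 1e-8)
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 1)),
                 class = "srx_zero_vector_warning")
  expect_equal(z, 0)
})

test_that("euclidean similarity is 1/(1 + d + 1e-9) and strictly decreasing in d", {
  expect_equal(euclidean_similarity(c(1, 2), c(1, 2)), 1 / (1 + 1e-9))
  expect_equal(euclidean_similarity(c(0, 0), c(1, 0)), 1 / (2 + 1e-9))
  d <- seq(0, 10, by = 0.5)
  sims <- vapply(d, function(dd) euclidean_similarity(0, dd), numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("RBF similarity matches the closed form and its limits", {
  expect_equal(rbf_similarity(c(1, 2), c(1, 2), gamma = 0.5), 1)
  expect_equal(rbf_similarity(0, 1, gamma = 1), exp(-1))
  expect_equal(rbf_similarity(c(0, 0), c(3, 4), gamma = 1e-9), 1,
               tolerance = 1e-6)
})

test_that("Gower similarity handles mixed types, ranges and missingness", {
  u <- full_feature_row(); v <- full_feature_row()
  ranges <- setNames(rep(10, length(feature_schema()$numeric)),
                     feature_schema()$numeric)
  expect_equal(gower_similarity(u, v, ranges), 1)

  # single comparable numeric feature, range 10, difference 5
  u1 <- tibble::tibble(gender = NA, ethnicity = NA, age_years = 20,
                       comorbidity_count = NA, los_1 = NA, gap_1 = NA,
                       drug_1 = NA, switch_1 = NA, los_2 = NA, gap_2 = NA,
                       drug_2 = NA, switch_2 = NA)
  v1 <- u1; v1$age_years <- 25
  expect_equal(gower_similarity(u1, v1, c(age_years = 10)), 0.5)

  # all-categorical records differing everywhere
  u2 <- u1; v2 <- u1
  u2$age_years <- NA
  v2$age_years <- NA
  u2$gender <- "M"; u2$ethnicity <- "White"
  v2$gender <- "F"; v2$ethnicity <- "Asian"
  expect_equal(gower_similarity(u2, v2, ranges), 0)

  both_empty <- u1; both_empty$age_years <- NA
  expect_error(gower_similarity(both_empty, both_empty, ranges),
               class = "srx_all_missing_error")
})

test_that("feature space is fitted on training data only and transforms purely", {
  train <- dplyr::bind_rows(
    full_feature_row(age = 20, gender = "M", ethnicity = "White"),
    full_feature_row(age = 30, gender = "F", ethnicity = "Black/African American"),
    full_feature_row(age = 40, gender = "M", ethnicity = "White"))
  fs <- fit_feature_space(train)
  X <- transform_features(fs, train)
  age_col <- X[, "age_years"]
  expect_equal(mean(age_col), 0, tolerance = 1e-12)
  expect_equal(sd(age_col), 1, tolerance = 1e-12)

  # unseen level encodes as an all-zero block
  test <- full_feature_row(ethnicity = "Asian")
  Xt <- transform_features(fs, test)
  eth_cols <- grep("^ethnicity=", colnames(Xt))
  expect_true(all(Xt[, eth_cols] == 0))

  # idempotent refit, pure transform
  fs2 <- fit_feature_space(train)
  expect_equal(fs2$center, fs$center)
  expect_equal(fs2$levels, fs$levels)
  expect_identical(transform_features(fs, test), Xt)
})

test_that("ReliefF rewards separating features and zeroes constant ones", {
  withr::with_seed(10, {
    n <- 60
    labels <- rep(c(0, 1), each = n / 2)
    X <- tibble::tibble(
      signal = labels * 4 + rnorm(n, 0, 0.3),
      noise = rnorm(n),
      constant = rep(1, n))
  })
  w <- relieff_weights(X, labels, n_neighbors = 10)
  expect_true(w[["signal"]] > w[["noise"]])
  expect_equal(w[["constant"]], 0)
  expect_true(all(w >= 0))
  expect_equal(mean(w), 1)
  expect_error(relieff_weights(X, rep(1, n)), class = "srx_single_class_error")

  # permuted labels: the separating feature loses its edge
  gaps <- withr::with_seed(11, vapply(1:5, function(i) {
    wp <- relieff_weights(X, sample(labels), n_neighbors = 10)
    wp[["signal"]] - wp[["noise"]]
  }, numeric(1)))
  expect_lt(mean(gaps), (w[["signal"]] - w[["noise"]]) / 3)
})

test_that("NCA reduces to Euclidean at zero iterations and separates planted classes", {
  withr::with_seed(12, {
    n <- 40
    labels <- rep(c(0, 1), each = n / 2)
    X <- cbind(discr = labels * 3 + rnorm(n, 0, 0.4),
               junk1 = rnorm(n, 0, 2), junk2 = rnorm(n, 0, 2))
  })
  id_fit <- nca_fit(X, labels, max_iter = 0)
  expect_identical(id_fit$transform, diag(3))

  fit <- nca_fit(X, labels, max_iter = 60, seed = 1)
  Z <- nca_transform(fit, X)
  D <- as.matrix(dist(Z))
  same <- outer(labels, labels, "=="); diag(same) <- NA
  expect_lt(mean(D[which(same)]), mean(D[which(!same)]))

  # bit-exact determinism for identical data and seed
  fit2 <- nca_fit(X, labels, max_iter = 60, seed = 1)
  expect_identical(fit$transform, fit2$transform)
})

test_that("all five fitted engines match brute-force formulas on small data", {
  withr::with_seed(13, {
    feats <- dplyr::bind_rows(lapply(1:10, function(i) {
      full_feature_row(age = runif(1, 18, 40), comorb = rpois(1, 3),
                       gender = sample(c("M", "F"), 1),
                       ethnicity = sample(retained_ethnicities(), 1))
    }))
    labels <- rep(c(TRUE, FALSE), 5)
  })
  q <- feats[1:4, ]
  sch <- feature_schema()

  for (m in c("cf_cosine", "cf_euclidean", "dr_rbf", "dr_nca")) {
    cfg <- if (m == "dr_nca") list(nca_max_iter = 0L) else list()
    model <- fit_similarity_model(m, feats, labels, config = cfg)
    S <- similarity_to_train(model, q)
    X <- transform_features(model$feature_space, feats)
    Q <- transform_features(model$feature_space, q)
    for (i in 1:4) for (j in 1:10) {
      want <- switch(m,
        cf_cosine = max(0, oracle_cosine(Q[i, ], X[j, ])),
        cf_euclidean = oracle_euclidean_sim(Q[i, ], X[j, ]),
        dr_rbf = oracle_rbf(Q[i, ], X[j, ], 1 / ncol(X)),
        dr_nca = oracle_euclidean_sim(Q[i, ], X[j, ]))
      expect_equal(S[i, j], want, tolerance = 1e-9,
                   label = sprintf("%s [%d,%d]", m, i, j))
    }
    # symmetry and range on the training pool itself
    St <- similarity_to_train(model, feats)
    expect_equal(St, t(St), tolerance = 1e-9)
    expect_true(all(St >= -1e-12 & St <= 1 + 1e-12))
  }

  model_g <- fit_similarity_model("dr_rba_gower", feats, labels)
  Sg <- similarity_to_train(model_g, q)
  for (i in 1:4) for (j in 1:10) {
    want <- oracle_gower(as.list(q[i, ]), as.list(feats[j, ]),
                         sch$categorical, sch$numeric,
                         as.list(model_g$gower_ranges),
                         as.list(model_g$feature_weights))
    expect_equal(Sg[i, j], want, tolerance = 1e-9)
  }
  Sgt <- similarity_to_train(model_g, feats)
  expect_equal(diag(Sgt), rep(1, 10), tolerance = 1e-9)
  expect_equal(Sgt, t(Sgt), tolerance = 1e-9)
})

test_that("self-similarity is 1 for cosine, Gower and RBF", {
  x <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(x, x), 1, tolerance = 1e-9)
  expect_equal(rbf_similarity(x, x, 0.1), 1, tolerance = 1e-9)
  u <- full_feature_row()
  ranges <- setNames(rep(5, length(feature_schema()$numeric)),
                     feature_schema()$numeric)
  expect_equal(gower_similarity(u, u, ranges), 1, tolerance = 1e-9)
})
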