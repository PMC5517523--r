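test_that("scatter matrices match hand arithmetic on a 2-D toy", {
  sc <- lda_scatter(toy_2d_features())
  expect_equal(sc$mu1, c(f1 = 1, f2 = 1 / 3))
  expect_equal(sc$mu2, c(f1 = 1, f2 = 7 / 3))
  expect_equal(unname(sc$S1), matrix(c(2, 0, 0, 2 / 3), 2, 2))
  expect_equal(sc$S_P, sc$S1 + sc$S2)
  expect_equal(unname(sc$S_B), matrix(c(0, 0, 0, 4), 2, 2))
})

test_that("a 4-point toy reproduces the textbook means and rank-one S_B", {
  df <- tibble::tibble(
    label = c("MG", "MG", "MN", "MN"),
    f1 = c(0, 2, 0, 2), f2 = c(0, 0, 1, 1)
  )
  sc <- lda_scatter(df)
  expect_equal(sc$mu1, c(f1 = 1, f2 = 0))
  expect_equal(sc$mu2, c(f1 = 1, f2 = 1))
  expect_equal(unname(sc$S_B), matrix(c(0, 0, 0, 1), 2, 2))
  expect_error(lda_scatter(df[c(1, 3, 4), ]), "at least 2")
})

test_that("scatter invariants hold on random data", {
  for (seed in 1:5) {
    corp <- generate_gaussian_corpus(n_per_class = 20, p = 6, seed = seed)
    sc <- lda_scatter(corp$features)
    expect_equal(sc$S_P, t(sc$S_P))
    expect_equal(sc$S_B, t(sc$S_B))
    expect_lte(qr(sc$S_B)$rank, 1)
    expect_true(all(eigen(sc$S_P, symmetric = TRUE,
      only.values = TRUE)$values > -1e-8))
  }
  # identical point sets in both classes: no between-class scatter
  df <- tibble::tibble(
    label = rep(c("MG", "MN"), each = 3),
    f1 = rep(c(0, 2, 1), 2), f2 = rep(c(0, 0, 1), 2)
  )
  expect_equal(max(abs(lda_scatter(df)$S_B)), 0)
})

test_that("the Fisher score is scale-invariant and matches hand arithmetic", {
  sc <- lda_scatter(toy_2d_features())
  # S_P = diag(4, 4/3), S_B = diag(0, 4)
  expect_equal(fisher_score(c(0, 1), sc), 3)
  expect_equal(fisher_score(c(1, 0), sc), 0)
  expect_equal(fisher_score(c(1, 1), sc), 4 / (4 + 4 / 3))
  for (c_ in c(-2, 0.5, 10)) {
    expect_equal(fisher_score(c_ * c(1, 1), sc), fisher_score(c(1, 1), sc))
  }
  # degenerate direction: the toy with zero within-class spread along f2
  df <- tibble::tibble(
    label = c("MG", "MG", "MN", "MN"),
    f1 = c(0, 2, 0, 2), f2 = c(0, 0, 1, 1)
  )
  sc2 <- lda_scatter(df)
  expect_error(fisher_score(c(0, 1), sc2), "null space")
})

test_that("closed-form w* beats random directions and finds planted features", {
  corp <- generate_gaussian_corpus(n_per_class = 200, delta = 1.5, seed = 21)
  sc <- lda_scatter(corp$features)
  fit <- fit_lda(corp$features)
  expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-9)
  J_star <- fisher_score(fit$w, sc)
  set.seed(22)
  for (i in 1:1000) {
    w <- rnorm(25)
    expect_lte(fisher_score(w / sqrt(sum(w^2)), sc), J_star + 1e-12)
  }

  # only feature 7 differs between classes
  set.seed(23)
  X <- matrix(rnorm(400 * 25), 400, 25)
  X[201:400, 7] <- X[201:400, 7] + 3
  colnames(X) <- feature_names()
  df <- dplyr::bind_cols(
    tibble::tibble(label = rep(c("MG", "MN"), each = 200)),
    tibble::as_tibble(X)
  )
  fit7 <- fit_lda(df)
  expect_equal(which.max(abs(fit7$w)), 7L, ignore_attr = TRUE)

  # coincident class means are degenerate
  same <- df
  same$label <- rep(c("MG", "MN"), 200)
  same[, 7] <- 0
  same[, -1] <- rbind(same[1:200, -1], same[1:200, -1])
  same$label <- rep(c("MG", "MN"), each = 200)
  expect_error(fit_lda(same), "coincide")
})

test_that("w* is parallel to an independent reference LDA direction", {
  for (seed in c(31, 32)) {
    corp <- generate_gaussian_corpus(n_per_class = 100, delta = 2, seed = seed)
    fit <- fit_lda(corp$features)
    X <- as.matrix(corp$features[, feature_names()])
    ref <- MASS::lda(x = X, grouping = corp$features$label)
    v <- ref$scaling[, 1]
    v <- v / sqrt(sum(v^2))
    expect_gt(abs(sum(v * fit$w)), 1 - 1e-6)
  }
})

test_that("projection is the plain inner product with stored scaling", {
  corp <- generate_gaussian_corpus(n_per_class = 50, seed = 41)
  fit <- fit_lda(corp$features)
  expect_equal(project_lda(fit, matrix(fit$w, nrow = 1)), 1) # self-projection
  expect_equal(project_lda(fit, rep(0, 25)), 0)
  a <- rnorm(25)
  b <- rnorm(25)
  expect_equal(
    project_lda(fit, a + b),
    project_lda(fit, a) + project_lda(fit, b)
  )
  expect_error(project_lda(fit, rep(0, 24)), "25")
})

test_that("classification picks the nearer projected centre; tau is midpoint", {
  corp <- generate_gaussian_corpus(n_per_class = 100, delta = 2, seed = 42)
  fit <- fit_lda(corp$features)
  expect_equal(fit$tau, mean(fit$mu_proj))
  expect_gt(fit$mu_proj[["MN"]], fit$mu_proj[["MG"]]) # sign convention

  sc <- lda_scatter(corp$features)
  pr1 <- predict(fit, matrix(sc$mu1, nrow = 1))
  expect_equal(pr1$call, "MG") # a training class mean is its own class
  pr2 <- predict(fit, matrix(sc$mu2, nrow = 1))
  expect_equal(pr2$call, "MN")

  # translation equivariance: shifting all points and the query together
  shift <- rnorm(25)
  df2 <- corp$features
  df2[, feature_names()] <- df2[, feature_names()] +
    matrix(shift, nrow(df2), 25, byrow = TRUE)
  fit2 <- fit_lda(df2)
  expect_equal(
    predict(fit2, matrix(sc$mu1 + shift, nrow = 1))$call,
    "MG"
  )
})

test_that("posteriors are normalized, monotone, and 1/2 at the threshold", {
  corp <- generate_gaussian_corpus(n_per_class = 100, delta = 2, seed = 43)
  fit <- fit_lda(corp$features)
  # a point projecting exactly at tau: posteriors (0.5, 0.5), tie call
  b_tau <- fit$tau * fit$w
  pr <- predict(fit, matrix(b_tau, nrow = 1), ambiguity = 0)
  expect_equal(pr$posterior_MG, 0.5)
  expect_equal(pr$posterior_MN, 0.5)
  expect_equal(pr$call, "ambiguous")
  pr_dual <- predict(fit, matrix(b_tau, nrow = 1), ambiguity = 0.05)
  expect_equal(pr_dual$call, "MG/MN")

  set.seed(44)
  Q <- matrix(rnorm(25 * 30), 30, 25)
  prs <- predict(fit, Q)
  expect_equal(prs$posterior_MG + prs$posterior_MN, rep(1, 30))
  expect_equal(order(prs$projection), order(prs$posterior_MN)) # monotone

  at_mu2 <- predict(fit, matrix(lda_scatter(corp$features)$mu2, nrow = 1))
  expect_gt(at_mu2$posterior_MN, 0.5)
})

test_that("leave-one-out is perfect on separable data and order-invariant", {
  df <- separable_features(10)
  cv <- loo_lda(df)
  expect_equal(unname(cv$per_class_accuracy), c(1, 1))
  expect_equal(colSums(cv$confusion), c(MG = 10, MN = 10))

  corp <- generate_gaussian_corpus(n_per_class = 25, delta = 1, seed = 51)
  cv1 <- loo_lda(corp$features)
  set.seed(511)
  shuffled <- corp$features[sample(nrow(corp$features)), ]
  cv2 <- loo_lda(shuffled)
  expect_equal(cv1$confusion, cv2$confusion)
  p1 <- cv1$predictions[order(cv1$predictions$site_id), ]
  p2 <- cv2$predictions[order(cv2$predictions$site_id), ]
  expect_equal(as.data.frame(p1), as.data.frame(p2), ignore_attr = TRUE)
})

test_that("LOO accuracy tracks the Gaussian closed form at small scale", {
  # projected-mean separation Delta with unit pooled SD: Bayes rate Phi(Delta/2)
  delta <- 2
  n <- 150
  corp <- generate_gaussian_corpus(n_per_class = n, delta = delta, seed = 52)
  cv <- loo_lda(corp$features)
  acc <- sum(diag(cv$confusion)) / sum(cv$confusion)
  target <- pnorm(delta / 2)
  se <- sqrt(target * (1 - target) / (2 * n))
  expect_lt(abs(acc - target), 4 * se + 0.02) # small-n estimation slack
})

test_that("feature importance ranks planted composition signals correctly", {
  atoms <- generate_site_structures(n_per_class = 100, enrichment = 4,
    seed = 53)
  f <- extract_features(atoms)
  fit <- fit_lda(f)
  imp <- lda_importance(fit)
  expect_setequal(imp$feature, names(fit$w)) # a permutation of all features
  expect_equal(sort(imp$rank), seq_len(25))
  his <- imp[imp$feature == "HIS", ]
  lys <- imp[imp$feature == "LYS", ]
  expect_lte(his$rank, 3)
  expect_equal(his$favored_class, "MN")
  expect_lte(lys$rank, 3)
  expect_equal(lys$favored_class, "MG")
})

test_that("features with identical class distributions are flagged neutral", {
  set.seed(54)
  X <- matrix(rnorm(300 * 4), 300, 4)
  X[151:300, 1] <- X[151:300, 1] + 4
  colnames(X) <- paste0("V", 1:4)
  df <- dplyr::bind_cols(
    tibble::tibble(label = rep(c("MG", "MN"), each = 150)),
    tibble::as_tibble(X)
  )
  imp <- lda_importance(fit_lda(df))
  expect_false(imp$neutral[imp$feature == "V1"])
  expect_true(any(imp$neutral[imp$feature != "V1"]))
})

test_that("fitted models serialize to JSON and back without loss", {
  corp <- generate_gaussian_corpus(n_per_class = 40, seed = 55)
  fit <- fit_lda(corp$features, standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(fit, path)
  back <- read_lda_model(path)
  expect_equal(back$w, fit$w)
  expect_equal(back$tau, fit$tau)
  expect_equal(back$sigma_pooled, fit$sigma_pooled)
  q <- matrix(rnorm(25), nrow = 1)
  expect_equal(predict(back, q), predict(fit, q))
})

test_that("tidy and glance summarise fits and cross-validations", {
  corp <- generate_gaussian_corpus(n_per_class = 30, delta = 3, seed = 56)
  fit <- fit_lda(corp$features)
  td <- tidy(fit)
  expect_equal(td$feature, feature_names())
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_gt(gl$separation, 0)
  cv <- loo_lda(corp$features)
  expect_equal(nrow(tidy(cv)), 60)
  expect_named(glance(cv),
    c("n", "accuracy", "accuracy_MG", "accuracy_MN", "n_unpredictable"))
})
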