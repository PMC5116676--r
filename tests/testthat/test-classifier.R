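# synthetic feature tables drawn directly from the generator's ratio law
sim_features <- function(n, medians, sdlog = 0.3) {
  stopifnot(setequal(names(medians), paste0("r", c(138, 145, 163, 168, 186,
                                                   274, 292, 325, 366))))
  out <- as.data.frame(lapply(medians, function(m) {
    rlnorm(n, meanlog = log(m), sdlog = sdlog)
  }))
  names(out) <- names(medians)
  out
}

base_medians <- c(r138 = 0.5, r145 = 0.1, r163 = 0.1, r168 = 0.2,
                  r186 = 0.3, r274 = 0.2, r292 = 0.2, r325 = 0.1,
                  r366 = 0.3)

test_that("training recovers a planted 186/204 separation", {
  set.seed(101)
  med_o <- base_medians; med_o["r186"] <- 1.0
  med_n <- base_medians; med_n["r186"] <- 0.1
  x <- rbind(sim_features(200, med_o), sim_features(200, med_n))
  y <- rep(c("O", "N"), each = 200)
  m <- suppressWarnings(train_classifier(x, y, seed = 1))
  expect_gt(m$weights[["r186"]], 0)
  expect_equal(mean(predict(m, x)$call == y), 1.0)
})

test_that("degenerate label sets are rejected", {
  set.seed(102)
  x <- sim_features(10, base_medians)
  expect_error(train_classifier(x, rep("N", 10)), "each class")
  expect_error(train_classifier(x, c("N", rep("O", 9))), "each class")
  expect_error(train_classifier(x[1:3, ], c("N", "O", "Q")), "labels")
})

test_that("duplicating every row leaves the MLE decision boundary unchanged", {
  set.seed(103)
  # heavy overlap so the unpenalized MLE exists
  med_o <- base_medians; med_o["r186"] <- 0.45
  x <- rbind(sim_features(150, med_o, sdlog = 1), sim_features(150, base_medians, sdlog = 1))
  y <- rep(c("O", "N"), each = 150)
  m1 <- train_classifier(x, y)
  m2 <- train_classifier(rbind(x, x), c(y, y))
  expect_false(m1$penalized)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-6)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-6)
})

test_that("prediction follows the sigmoid with ties assigned to O", {
  m <- structure(
    list(weights = setNames(rep(0, 9), paste0("r", c(138, 145, 163, 168, 186,
                                                     274, 292, 325, 366))),
         intercept = 0, feature_order = paste0("r", c(138, 145, 163, 168, 186,
                                                      274, 292, 325, 366)),
         positive_class = "O", penalized = FALSE, ridge = 0,
         training_meta = list()),
    class = "glyco_logit"
  )
  x0 <- as.data.frame(as.list(setNames(rep(0, 9), m$feature_order)))
  p <- predict(m, x0)
  expect_equal(p$p_o, 0.5)
  expect_identical(p$call, "O")          # boundary tie goes to O
  expect_equal(p$probability, 0.5)

  m$intercept <- -2                      # all-zero ratios: sign of intercept
  expect_identical(predict(m, x0)$call, "N")
  expect_equal(predict(m, x0)$probability, plogis(2))

  # probability conservation: p(N) + p(O) = 1 exactly
  set.seed(104)
  m$intercept <- 0.3
  m$weights[] <- rnorm(9)
  xr <- sim_features(50, base_medians)
  pr <- predict(m, xr)
  expect_true(all(pr$probability >= 0.5))
  expect_equal(pr$probability + (1 - pmax(pr$p_o, 1 - pr$p_o)), rep(1, 50))
})

test_that("p(O) is monotone in r186 when its weight is positive", {
  set.seed(105)
  med_o <- base_medians; med_o["r186"] <- 1.0
  x <- rbind(sim_features(150, med_o), sim_features(150, base_medians))
  y <- rep(c("O", "N"), each = 150)
  m <- suppressWarnings(train_classifier(x, y))
  expect_gt(m$weights[["r186"]], 0)
  grid <- x[rep(1, 25), ]
  grid$r186 <- seq(0, 5, length.out = 25)
  p <- predict(m, grid)$p_o
  expect_true(all(diff(p) >= 0))
})

test_that("cross-validation is stratified, deterministic and honest", {
  set.seed(106)
  med_o <- base_medians; med_o["r186"] <- 2.0
  x <- rbind(sim_features(80, med_o, 0.2), sim_features(120, base_medians, 0.2))
  y <- rep(c("O", "N"), c(80, 120))
  r1 <- cross_validate(x, y, k_folds = 10, seed = 3)
  expect_equal(r1$overall_accuracy, 1.0)
  expect_equal(sum(r1$confusion), 200)
  r2 <- cross_validate(x, y, k_folds = 10, seed = 3)
  expect_identical(r1$overall_accuracy, r2$overall_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(cross_validate(x[1:12, ], y[c(1:6, 81:86)], k_folds = 10),
               "k_folds")
})

test_that("Wald p-values flag the planted feature and stay null-uniform", {
  set.seed(107)
  # only r186 separates (overlapping classes so the MLE exists)
  med_o <- base_medians; med_o["r186"] <- 0.9
  med_n <- base_medians; med_n["r186"] <- 0.25
  x <- rbind(sim_features(300, med_o, 0.5), sim_features(300, med_n, 0.5))
  y <- rep(c("O", "N"), each = 300)
  m <- suppressWarnings(train_classifier(x, y))
  p <- feature_significance(m, x, y)
  expect_identical(names(which.min(p)), "r186")

  # pure-noise features give uniform p-values across simulations
  pvals <- replicate(120, {
    xn <- sim_features(400, base_medians)
    yn <- sample(rep(c("N", "O"), each = 200))
    fit <- suppressWarnings(train_classifier(xn, yn))
    feature_significance(fit, xn, yn)[["r163"]]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Wald p-values sharpen with sample size for a fixed effect", {
  set.seed(108)
  med_o <- base_medians; med_o["r186"] <- 0.6
  med_n <- base_medians; med_n["r186"] <- 0.35
  p_at_n <- vapply(c(200, 800, 3200), function(n) {
    p_reps <- vapply(1:5, function(i) {
      x <- rbind(sim_features(n / 2, med_o, 0.5),
                 sim_features(n / 2, med_n, 0.5))
      y <- rep(c("O", "N"), each = n / 2)
      feature_significance(train_classifier(x, y), x, y)[["r186"]]
    }, numeric(1))
    median(p_reps)
  }, numeric(1))
  expect_true(all(diff(log(p_at_n)) < 0))
})

test_that("fitted coefficients fall within 3 SE of the generating model", {
  set.seed(109)
  beta <- c(`(Intercept)` = -0.5, r138 = 0.8, r145 = 0, r163 = -1.2,
            r168 = 0, r186 = 2.5, r274 = 0.6, r292 = 0, r325 = -0.5,
            r366 = 0)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    x <- sim_features(5000, base_medians, 0.5)
    eta <- beta[1] + as.matrix(x) %*% beta[-1]
    y <- ifelse(runif(5000) < plogis(eta), "O", "N")
    m <- train_classifier(x, y)
    se <- sqrt(diag(m$vcov))
    est <- c(m$intercept, m$weights)
    hits <- hits + sum(abs(est - beta) <= 3 * se)
    total <- total + length(beta)
  }
  expect_gte(hits / total, 0.95)
})

test_that("model JSON round-trips exactly and validates its schema", {
  set.seed(110)
  med_o <- base_medians; med_o["r186"] <- 1.0
  x <- rbind(sim_features(60, med_o), sim_features(60, base_medians))
  y <- rep(c("O", "N"), each = 60)
  m <- suppressWarnings(train_classifier(x, y, seed = 42))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, x), predict(m2, x))
  expect_equal(m2$weights, m$weights)

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 40), path)
  expect_error(load_model(path))

  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m, path2)
  j <- jsonlite::read_json(path2)
  j$weights$r186 <- NULL
  jsonlite::write_json(j, path2, auto_unbox = TRUE)
  expect_error(load_model(path2), "9 oxonium")
})
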