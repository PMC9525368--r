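# Correlations, residual independence, AUC, VIF, BH adjustment.

test_that("Pearson correlation matches the direct covariance formula on a hand example", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:5), 2),
    quantifier = rep(c("SUVr", "SI"), each = 5),
    region = "global", value = c(x, y), flag = NA_character_
  )
  pm <- pearson_matrix(tab)
  expect_equal(pm$rho, oracle, tolerance = 1e-12)
  expect_equal(pm$n, 5)
})

test_that("Pearson correlation is 1 for affine pairs and ~0 for independent ones", {
  y <- rnorm(50)
  tab <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:50), 2),
    quantifier = rep(c("SUVr", "SI"), each = 50),
    region = "global", value = c(2 * y + 1, y), flag = NA_character_
  )
  expect_equal(pearson_matrix(tab)$rho, 1, tolerance = 1e-12)
  withr::with_seed(3, {
    tab$value[1:50] <- rnorm(50)
  })
  expect_lt(abs(pearson_matrix(tab)$rho), 0.3)
})

test_that("constant columns are reported as missing with a reason, not an error", {
  tab <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:5), 2),
    quantifier = rep(c("SUVr", "SI"), each = 5),
    region = "global", value = c(rep(1, 5), rnorm(5)), flag = NA_character_
  )
  pm <- pearson_matrix(tab)
  expect_true(is.na(pm$rho))
  expect_match(pm$note, "constant")
})

test_that("Pearson rho and AUC are invariant under z-scoring", {
  sc <- dplyr::filter(test_scores_small(), region == "global")
  md <- test_cohort_small()$metadata
  z <- zscore_scores(sc)
  expect_equal(pearson_matrix(z)$rho, pearson_matrix(sc)$rho, tolerance = 1e-10)
  for (q in c("SUVr", "SI")) {
    raw <- dplyr::filter(sc, quantifier == q)
    zs <- dplyr::filter(z, quantifier == q)
    labs <- md$class_label[match(raw$subject_id, md$subject_id)]
    expect_equal(mann_whitney_auc(zs$value, labs),
                 mann_whitney_auc(raw$value, labs), tolerance = 1e-12)
  }
})

test_that("OLS residuals are orthogonal to their predictor and the refit matches the null model", {
  sc <- zscore_scores(dplyr::filter(test_scores_small(), region == "global"))
  ri <- residual_independence(sc)
  expect_equal(nrow(ri$pairs), 6)
  expect_true(all(abs(ri$pairs$resid_predictor_cor) < 1e-10))
  expect_true(all(abs(ri$pairs$refit_slope) < 1e-10))
  expect_true(all(ri$pairs$refit_r_squared < 1e-10))
  expect_equal(nrow(ri$cross), 12)  # 6 pairs x 2 remaining quantifiers
})

test_that("cross-pair residual correlations match a direct computation under a shared latent", {
  withr::with_seed(11, {
    lat <- rnorm(60)
    m <- cbind(SUVr = lat + rnorm(60, 0, 0.4), ELBA = lat + rnorm(60, 0, 0.4),
               TDr = lat + rnorm(60, 0, 0.4), WMR = lat + rnorm(60, 0, 0.4))
  })
  tab <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:60), 4),
    quantifier = rep(colnames(m), each = 60),
    region = "global", value = as.vector(m), flag = NA_character_
  )
  ri <- residual_independence(tab)
  res <- stats::residuals(stats::lm(m[, "SUVr"] ~ m[, "ELBA"]))
  oracle <- stats::cor(res, m[, "TDr"])
  got <- ri$cross$resid_third_cor[ri$cross$response == "SUVr" &
                                  ri$cross$predictor == "ELBA" &
                                  ri$cross$third == "TDr"]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("AUC point estimate equals brute-force pair counting", {
  # {neg: 0.1, 0.2; pos: 0.15, 0.3} -> 3 of 4 pairs
  expect_equal(mann_whitney_auc(c(0.1, 0.2, 0.15, 0.3),
                                c("negative", "negative", "positive", "positive")),
               0.75)
  # randomized inputs vs. explicit double loop, including ties
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(6:30, 1)
      labs <- c(rep("negative", 3), rep("positive", 3),
                sample(c("negative", "positive"), n - 6, replace = TRUE))
      x <- round(rnorm(n), 1)  # coarse rounding forces ties
    })
    pos <- x[labs == "positive"]; neg <- x[labs == "negative"]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(mann_whitney_auc(x, labs), brute, tolerance = 1e-12)
  }
})

test_that("bootstrap AUC handles separation, null shuffling and determinism", {
  scores <- c(rnorm(20, 0), rnorm(15, 10))
  labs <- rep(c("negative", "positive"), c(20, 15))
  res <- auc_bootstrap(scores, labs, n_boot = 100, seed = 4)
  expect_equal(res$auc, 1)
  expect_equal(unname(res$auc_ci), c(1, 1))

  null_aucs <- vapply(1:10, function(s) {
    withr::with_seed(s, shuffled <- sample(labs))
    auc_bootstrap(scores, shuffled, n_boot = 50, seed = 4)$auc_mean
  }, 0)
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)

  r1 <- auc_bootstrap(scores, labs, n_boot = 50, seed = 12)
  r2 <- auc_bootstrap(scores, labs, n_boot = 50, seed = 12)
  expect_identical(glance(r1), glance(r2))
  expect_error(auc_bootstrap(scores, rep("negative", 35)), "per class")
})

test_that("VIF matches its closed form and flags collinearity", {
  x1 <- scale(rnorm(100))[, 1]
  e <- stats::residuals(stats::lm(rnorm(100) ~ x1))
  x2 <- 0.4 * x1 + sqrt(1 - 0.16) * scale(e)[, 1]  # empirical r exactly 0.4
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.4^2), 2), tolerance = 1e-10)

  # orthogonal covariates -> VIF 1
  x3 <- scale(e)[, 1]
  v2 <- vif(cbind(a = x1, b = x3))
  expect_equal(unname(v2), c(1, 1), tolerance = 1e-10)

  expect_warning(v3 <- vif(cbind(a = x1, b = x1)), "collinearity")
  expect_true(all(is.infinite(v3)))
})

test_that("BH adjustment matches hand step-up and is permutation-equivariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.8, 0.04, 0.2)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals exhaustive step-up enumeration for short p-vectors", {
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  withr::with_seed(2, {
    for (len in 1:6) {
      for (rep in 1:20) {
        p <- sample(grid, len, replace = TRUE)
        expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
      }
    }
  })
})
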