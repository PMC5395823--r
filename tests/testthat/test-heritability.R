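test_that("pair tables are validated with informative errors", {
  tab <- simulate_twin_traits(5, 5, a2 = 0.5, seed = 1)
  expect_silent(twin_pair_table(tab))
  bad <- tab
  bad$zygosity[3] <- "XX"
  expect_error(twin_pair_table(bad), "zygosity token in row 3")
  dup <- tab
  dup$pair_id[2] <- dup$pair_id[1]
  expect_error(twin_pair_table(dup), "unique")
})

test_that("twin model fits recover parameters and obey the h2 formula", {
  tab <- simulate_twin_traits(5000, 5000, a2 = 0.7, seed = 11)
  fit <- fit_twin_sem(tab, "AE", use_age = FALSE, se = TRUE)
  expect_equal(fit$h2, 0.7, tolerance = 0.03)
  expect_equal(fit$h2, fit$a^2 / (fit$a^2 + fit$e^2), tolerance = 1e-9)
  expect_true(fit$h2_se > 0 && fit$h2_se < 0.05)
  # AIC identity holds exactly
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_params)
  # an AE fit with a = e has h2 = 1/2 by the formula
  tab5 <- simulate_twin_traits(2000, 2000, a2 = 0.5, seed = 3)
  f5 <- fit_twin_sem(tab5, "AE", use_age = FALSE)
  expect_equal(f5$a^2 / (f5$a^2 + f5$e^2), f5$h2)
  expect_equal(f5$h2, 0.5, tolerance = 0.05)
})

test_that("the E model equals the closed-form independent-normal likelihood", {
  tab <- simulate_twin_traits(100, 100, a2 = 0.4, seed = 5)
  fe <- fit_twin_sem(tab, "E", use_age = FALSE)
  vals <- c(tab$value_twin1, tab$value_twin2)
  mu <- mean(vals); v <- mean((vals - mu)^2)
  expect_equal(fe$loglik, sum(dnorm(vals, mu, sqrt(v), log = TRUE)),
               tolerance = 1e-9)
  expect_equal(fe$h2, 0)
  expect_equal(fe$a, 0)
})

test_that("the model ladder is properly nested and the saturated fit dominates", {
  tab <- simulate_twin_traits(300, 300, a2 = 0.5, age_beta = 0.02, seed = 7)
  for (use_age in c(TRUE, FALSE)) {
    sat <- fit_saturated(tab, use_age = use_age)
    ace <- fit_twin_sem(tab, "ACE", use_age = use_age)
    ae <- fit_twin_sem(tab, "AE", use_age = use_age)
    e <- fit_twin_sem(tab, "E", use_age = use_age)
    expect_gte(sat$loglik, ace$loglik - 1e-6)
    expect_gte(ace$loglik, ae$loglik - 1e-6)
    expect_gte(ae$loglik, e$loglik - 1e-6)
  }
  expect_equal(fit_saturated(tab, use_age = TRUE)$n_params, 11L)
  expect_equal(fit_saturated(tab, use_age = FALSE)$n_params, 10L)
})

test_that("moment-matched data lets the structured model attain the saturated fit", {
  # construct data whose group sample moments are EXACTLY exchangeable and
  # equal across zygosity (ML variance scale), so an ACE structure (a2 = 0,
  # c2 = cov) reproduces the saturated moments
  make_group <- function(n, zyg, target_cov = 0.3, offset = 0) {
    set.seed(17 + offset)
    x <- matrix(rnorm(2 * n), n, 2)
    x <- sweep(x, 2, colMeans(x))
    # whiten exactly (ML covariance), then color to the target
    S <- crossprod(x) / n
    x <- x %*% solve(chol(S))
    target <- matrix(c(1, target_cov, target_cov, 1), 2)
    x <- x %*% chol(target)
    data.frame(pair_id = paste0(zyg, seq_len(n)), zygosity = zyg,
               value_twin1 = x[, 1], value_twin2 = x[, 2],
               age_twin1 = NA_real_, age_twin2 = NA_real_)
  }
  tab <- rbind(make_group(40, "MZ"), make_group(40, "DZ", offset = 1))
  sat <- fit_saturated(tab, use_age = FALSE)
  ace <- fit_twin_sem(tab, "ACE", use_age = FALSE)
  expect_lt(sat$loglik - ace$loglik, 1e-4)
  gof <- goodness_of_fit(ace, sat)
  expect_gte(gof$stat, 0)
  expect_gt(gof$p_value, 0.99)
})

test_that("goodness of fit behaves at the boundary and detects misfit direction", {
  tab <- simulate_twin_traits(200, 200, a2 = 0.5, seed = 9)
  sat <- fit_saturated(tab, use_age = FALSE)
  self_test <- goodness_of_fit(sat, sat)
  expect_equal(self_test$stat, 0)
  expect_equal(self_test$p_value, 1)
  ae <- fit_twin_sem(tab, "AE", use_age = FALSE)
  g <- goodness_of_fit(ae, sat)
  expect_gte(g$stat, 0)
  expect_equal(g$df, sat$n_params - ae$n_params)
  suppressWarnings(expect_error(goodness_of_fit(sat, ae), "nested"))
})

test_that("AIC model selection lands in the ladder and finds the truth often", {
  set.seed(23)
  hits <- 0
  for (r in 1:20) {
    tab <- simulate_twin_traits(300, 300, a2 = 0.6)
    sel <- select_model(tab, use_age = FALSE)
    expect_true(sel$best$model %in% c("ACE", "AE", "E"))
    hits <- hits + (sel$best$model == "AE")
  }
  expect_gt(hits / 20, 0.7)                  # AE truth selected usually
})

test_that("h2 is invariant to affine rescaling of the trait", {
  tab <- simulate_twin_traits(300, 300, a2 = 0.5, age_beta = 0.01, seed = 13)
  f1 <- fit_twin_sem(tab, "AE", use_age = TRUE)
  tab2 <- tab
  tab2$value_twin1 <- 13.7 * tab$value_twin1 + 5
  tab2$value_twin2 <- 13.7 * tab$value_twin2 + 5
  f2 <- fit_twin_sem(tab2, "AE", use_age = TRUE)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
})

test_that("mass_univariate handles many traits, copies, and mismatches", {
  set.seed(15)
  n_pairs <- 60
  tab <- simulate_twin_traits(n_pairs / 2, n_pairs / 2, a2 = 0.6)
  subjects <- data.frame(
    subject_id = seq_len(2 * n_pairs),
    pair_id = rep(seq_len(n_pairs), each = 2),
    zygosity = rep(tab$zygosity, each = 2),
    age = rep(tab$age_twin1, each = 2))
  vals <- as.vector(rbind(tab$value_twin1, tab$value_twin2))
  tm <- cbind(a = vals, b = vals, c = rnorm(2 * n_pairs))
  res <- mass_univariate(tm, subjects, use_age = FALSE)
  expect_equal(nrow(res), 3L)
  expect_equal(res$h2[1], res$h2[2])          # identical traits, identical rows
  expect_equal(res$AIC[1], res$AIC[2])
  expect_true(all(res$converged))
  expect_error(mass_univariate(tm[1:5, ], subjects, use_age = FALSE),
               "does not match")
})

test_that("heritability maps render the absolute scale and validate inputs", {
  avg <- matrix(rnorm(24), 8, 3)
  path <- tempfile(fileext = ".ply")
  heritability_map(rep(0, 8), avg, path)
  lines <- readLines(path)
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  cols <- unique(vapply(strsplit(body, " "), function(x)
    paste(x[4:6], collapse = ","), ""))
  expect_length(cols, 1)                      # all-zero map: one uniform color
  h2 <- rep(0, 8); h2[3] <- 1
  heritability_map(h2, avg, path)
  csv <- read.csv(paste0(path, ".csv"))
  expect_equal(csv$h2, h2)
  expect_error(heritability_map(c(rep(0, 7), 1.2), avg, path), "\\[0, 1\\]")
  expect_error(heritability_map(rep(0.5, 4), avg, path), "one h2 per")
})

test_that("the zero-heritability test has correct size and detects signal", {
  ps0 <- power_simulation(200, 200, h2_true = 0, n_replicates = 400,
                          seed = 31)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(ps0$rate - 0.05), 3 * se)
  ps1 <- power_simulation(100, 100, h2_true = 0.6, n_replicates = 100,
                          seed = 32)
  expect_gt(ps1$rate, 0.9)
  expect_equal(ps0$se, sqrt(ps0$rate * (1 - ps0$rate) / 400))
})
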