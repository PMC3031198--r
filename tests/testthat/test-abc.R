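toy_table <- function(ss, extra = NULL) {
  tbl <- tibble::tibble(sim = seq_len(nrow(ss)))
  if (!is.null(extra)) tbl <- dplyr::bind_cols(tbl, extra)
  dplyr::bind_cols(tbl, tibble::as_tibble(ss))
}

test_that("unit-variance scaling divides by the table SD and drops constants", {
  ss <- tibble::tibble(ss_a = c(2, 4, 6), ss_b = c(1, 1, 1))
  tbl <- toy_table(ss)
  obs <- c(ss_a = 4, ss_b = 1)
  std <- abc_standardize(tbl, obs)
  expect_equal(unname(std$ss[, "ss_a"]), c(1, 2, 3))
  expect_equal(std$dropped, "ss_b")
  expect_equal(unname(std$obs), 2)
  # retained coordinates have unit variance
  expect_lt(abs(sd(std$ss[, "ss_a"]) - 1), 1e-9)
  all_const <- toy_table(tibble::tibble(ss_a = c(1, 1), ss_b = c(2, 2)))
  expect_error(abc_standardize(all_const, c(ss_a = 1, ss_b = 2)),
               "zero variance")
})

test_that("rejection equals exhaustive nearest-neighbour selection", {
  set.seed(41)
  ss <- tibble::tibble(ss_a = c(0, 1, 2, 3, 10), ss_b = c(0, 1, 0, 1, 5))
  tbl <- toy_table(ss, tibble::tibble(e_tau = 1:5))
  obs <- c(ss_a = 2.1, ss_b = 0.1)
  std <- abc_standardize(tbl, obs)
  post <- abc_reject(std, 2)
  # brute force over all rows on the scaled coordinates
  dists <- sqrt(colSums((t(std$ss) - std$obs)^2))
  expect_equal(post$meta$sim, order(dists)[1:2])
  expect_equal(post$dist, sort(dists)[1:2])
  expect_true(which.max(post$weight) == which.min(post$dist))
  expect_true(all(post$weight >= 0 & post$weight <= 1))

  # observation equal to a row: distance 0, always accepted
  std0 <- abc_standardize(tbl, c(ss_a = 3, ss_b = 1))
  post0 <- abc_reject(std0, 1)
  expect_equal(post0$meta$sim, 4)
  expect_equal(post0$dist, 0)

  # accepting everything returns the whole table
  expect_equal(nrow(abc_reject(std, 5)$meta), 5)
})

test_that("local-linear adjustment is exact on noiseless linear targets", {
  set.seed(42)
  x <- runif(40, -2, 2)
  y <- runif(40, -1, 1)
  theta <- 1.5 + 2 * x - 0.5 * y
  tbl <- toy_table(tibble::tibble(ss_x = x, ss_y = y),
                   tibble::tibble(e_tau = theta))
  obs <- c(ss_x = 0.3, ss_y = -0.4)
  std <- abc_standardize(tbl, obs)
  post <- abc_reject(std, 20)
  post <- abc_adjust_loclinear(post, targets = "e_tau")
  expect_equal(post$adjusted$e_tau,
               rep(1.5 + 2 * 0.3 - 0.5 * (-0.4), 20), tolerance = 1e-9)

  # accepted set at the observed point: adjusted equals raw
  tbl2 <- toy_table(tibble::tibble(ss_x = c(rep(1, 5), 2, 3),
                                   ss_y = c(rep(2, 5), 0, 1)),
                    tibble::tibble(e_tau = c(4, 4.5, 5, 5.5, 6, 1, 2)))
  std2 <- abc_standardize(tbl2, c(ss_x = 1, ss_y = 2))
  post2 <- abc_reject(std2, 5)
  expect_warning(post2 <- abc_adjust_loclinear(post2, targets = "e_tau"),
                 "singular")
  expect_equal(post2$adjusted$e_tau, c(4, 4.5, 5, 5.5, 6))
})

test_that("local-linear adjustment matches a normal-equations oracle", {
  set.seed(43)
  n <- 6
  X <- cbind(runif(n), runif(n))
  theta <- 2 + X %*% c(1, -1) + rnorm(n, 0, 0.3)
  tbl <- toy_table(tibble::tibble(ss_x = X[, 1], ss_y = X[, 2]),
                   tibble::tibble(e_tau = drop(theta)))
  obs <- c(ss_x = 0.5, ss_y = 0.5)
  std <- abc_standardize(tbl, obs)
  post <- abc_reject(std, n)
  post <- abc_adjust_loclinear(post, targets = "e_tau")
  Xc <- sweep(post$ss, 2, post$obs, "-")
  W <- diag(post$weight)
  D <- cbind(1, Xc)
  beta <- solve(t(D) %*% W %*% D, t(D) %*% W %*% post$meta$e_tau)
  expect_equal(post$adjusted$e_tau,
               drop(post$meta$e_tau - Xc %*% beta[-1]), tolerance = 1e-8)

  # truncation to prior support
  post_tr <- abc_adjust_loclinear(post, targets = "e_tau",
                                  bounds = list(e_tau = c(2.2, 2.4)))
  expect_true(all(post_tr$adjusted$e_tau >= 2.2 - 1e-12 &
                    post_tr$adjusted$e_tau <= 2.4 + 1e-12))
})

test_that("polychotomous regression recovers pure, uninformative and separable cases", {
  set.seed(44)
  # single category among accepted rows: probability 1
  tbl <- toy_table(tibble::tibble(ss_x = rnorm(30)),
                   tibble::tibble(z = rep(2L, 30)))
  std <- abc_standardize(tbl, c(ss_x = 0))
  post <- abc_reject(std, 30)
  pr <- abc_adjust_polychotomous(post, "z", levels = c("1", "2", "3"))
  expect_equal(unname(pr), c(0, 1, 0))

  # labels independent of the coordinates: close to accepted frequencies
  n <- 400
  tbl2 <- toy_table(tibble::tibble(ss_x = rnorm(n)),
                    tibble::tibble(z = sample(1:2, n, TRUE, c(0.7, 0.3))))
  std2 <- abc_standardize(tbl2, c(ss_x = 0))
  post2 <- abc_reject(std2, n)
  pr2 <- abc_adjust_polychotomous(post2, "z")
  raw <- as.numeric(table(factor(post2$meta$z, 1:2))) / n
  expect_lt(max(abs(pr2 - raw)), 0.1)

  # well-separated clusters, observation inside cluster 1
  ss3 <- c(rnorm(50, -5, 0.3), rnorm(50, 5, 0.3))
  tbl3 <- toy_table(tibble::tibble(ss_x = ss3),
                    tibble::tibble(z = rep(1:2, each = 50)))
  std3 <- abc_standardize(tbl3, c(ss_x = -5))
  post3 <- abc_reject(std3, 100)
  pr3 <- abc_adjust_polychotomous(post3, "z")
  expect_gt(pr3["1"], 0.95)
})

test_that("the KDE posterior mode handles constants, peaks and boundaries", {
  expect_equal(posterior_mode(rep(3.3, 10)), 3.3)
  set.seed(45)
  x <- rnorm(1e4, 5, 1)
  expect_lt(abs(posterior_mode(x) - 5), 0.1)
  h <- abs(rnorm(5e3))  # half-normal: true mode at 0
  expect_lt(abs(posterior_mode(h, bounds = c(0, Inf))), 0.05)
})

test_that("Bayes factors reproduce posterior/prior odds ratios", {
  # discrete uniform prior on {1,2,3} gives prior Pr = 1/3
  expect_equal(round(bayes_factor(0.58, 1 / 3), 2), 2.76)
  expect_equal(bayes_factor(0.25, 0.25), 1)
  expect_equal(bayes_factor(0.8, 0.5), 4)
  expect_identical(bayes_factor(1, 0.5), Inf)
  expect_identical(bayes_factor(0, 0.5), 0)
  expect_error(bayes_factor(0.5, 1), "prior")
})

test_that("mixed-model weighting matches per-model posterior averaging", {
  z <- c("iso", "iso", "iso", "mig", "mig")
  vals <- c(1, 2, 3, 10, 20)
  probs <- c(iso = 0.75, mig = 0.25)
  w <- mixed_model_weights(z, probs)
  expect_equal(sum(w), 1)
  mixed_mean <- sum(w * vals)
  per_model <- 0.75 * mean(vals[z == "iso"]) + 0.25 * mean(vals[z == "mig"])
  expect_equal(mixed_mean, per_model)
})

test_that("abc_fit returns coherent posterior summaries and tidiers", {
  set.seed(46)
  cfg <- sampling_config(config_template(3, 2, n1 = 3, n2 = 3, L = 400))
  prior <- prior_spec(migration_models = tibble::tibble(
    label = c("isolation", "migration"), nm_lo = c(0, 0), nm_hi = c(0, 2)))
  ref <- simulate_reference_table(cfg, prior, 1500, classes = c("pi_b", "psi_w"))
  pods <- generate_pods(cfg, prior, 1, classes = c("pi_b", "psi_w"))
  fit <- abc_fit(ref, pods[, ss_cols_test(pods)], n_accept = 100, prior = prior)
  expect_s3_class(fit, "habc_fit")
  expect_equal(sum(fit$discrete$psi$adjusted), 1, tolerance = 1e-6)
  expect_equal(sum(fit$discrete$z$raw), 1, tolerance = 1e-12)
  expect_true(fit$modes["omega"] >= 0)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 100)
  gl <- glance(fit)
  expect_equal(gl$n_accept, 100)
  expect_true(is.finite(gl$pr_psi1))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
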