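test_that("divergence-time assignment always uses exactly Psi distinct times", {
  set.seed(101)
  # Psi = 1: all pairs share one time, Omega = 0
  pt <- draw_psi_and_tau(5, c(0, 5), psi_fixed = 1)
  expect_equal(length(unique(pt$tau)), 1)
  expect_equal(hyper_summaries(pt$tau)$omega, 0)
  # Psi = Y: all distinct (continuous draws)
  pt <- draw_psi_and_tau(5, c(0, 5), psi_fixed = 5)
  expect_equal(length(unique(pt$tau)), 5)
  # Psi = 2 over many draws: always exactly 2 distinct values, each used
  for (i in 1:10000) {
    tau <- draw_psi_and_tau(5, c(0, 5), psi_fixed = 2)$tau
    u <- unique(tau)
    if (length(u) != 2 || !all(table(match(tau, u)) >= 1)) {
      fail(sprintf("draw %d produced %d distinct values", i, length(u)))
    }
  }
  succeed()
  expect_error(draw_psi_and_tau(5, c(0, 5), psi_fixed = 6), "1..Y")
})

test_that("Psi prior is discrete uniform on 1..Y", {
  set.seed(202)
  Y <- 7
  psi <- replicate(2e4, draw_psi_and_tau(Y, c(0, 1))$psi)
  tab <- tabulate(psi, Y)
  p <- stats::chisq.test(tab, p = rep(1 / Y, Y))$p.value
  expect_gt(p, 0.001)
})

test_that("taxon parameters respect their ranges and degenerate priors", {
  prior <- prior_spec(theta_a_range = c(0.002, 0.002),
                      theta_b_range = c(0.005, 0.005),
                      size_frac_range = c(0.5, 0.5),
                      time_frac_range = c(0.25, 0.25))
  tp <- draw_taxon_params(prior, tau = c(2, 4), nm_range = c(0, 0))
  expect_equal(tp$theta_a, c(0.002, 0.002))
  expect_equal(tp$theta_a1, c(0.001, 0.001))
  expect_equal(tp$tau_b1, c(0.5, 1))
  expect_true(all(tp$nm == 0))
  expect_true(all(tp$tau_b1 <= tp$tau & tp$tau_b2 <= tp$tau))

  set.seed(303)
  prior2 <- prior_spec(theta_a_range = c(0.5, 1.5))
  th <- draw_taxon_params(prior2, tau = rep(1, 1e4))$theta_a
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 1), 3 * se)
})

test_that("rate scalars have gamma moments, honour flags and fixed values", {
  set.seed(404)
  sc <- draw_locus_scalars(c(1, 20), 4, rate_het = FALSE)
  expect_equal(sc$scalars, rep(1, 4))

  sc2 <- draw_locus_scalars(c(20, 20), 1e5, rate_het = TRUE)
  x <- sc2$scalars
  se_m <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 1), 3 * se_m)
  # var of sample variance approx 2 sigma^4 / n for near-normal gamma(20)
  se_v <- sqrt(2 / length(x)) * (1 / 20)
  expect_lt(abs(stats::var(x) - 1 / 20), 3 * se_v)

  sc3 <- draw_locus_scalars(c(1, 20), 2, fixed = c(0.5, 1.5))
  expect_equal(sc3$scalars, c(0.5, 1.5))
  expect_error(draw_locus_scalars(c(1, 20), 3, fixed = c(1, 2)), "per locus")
})

test_that("model indicator is uniform over the candidate models", {
  mm1 <- tibble::tibble(label = "only", nm_lo = 0, nm_hi = 0)
  expect_equal(replicate(20, draw_model_indicator(mm1)), rep(1L, 20))
  mm3 <- tibble::tibble(label = c("a", "b", "c"), nm_lo = 0, nm_hi = 0)
  set.seed(505)
  z <- replicate(3e4, draw_model_indicator(mm3))
  freq <- tabulate(z, 3) / 3e4
  se <- sqrt((1 / 3) * (2 / 3) / 3e4)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  mm2 <- tibble::tibble(label = c("iso", "mig"), nm_lo = c(0, 0), nm_hi = c(0, 1))
  expect_true(all(replicate(50, draw_model_indicator(mm2)) %in% 1:2))
})

test_that("hyper draws are seed-deterministic and internally consistent", {
  cfg <- sampling_config(config_template(4, 3, n1 = 3, n2 = 3, L = 100))
  prior <- prior_spec(migration_models = tibble::tibble(
    label = c("iso", "mig"), nm_lo = c(0, 0), nm_hi = c(0, 5)))
  set.seed(606)
  h1 <- draw_hyper(cfg, prior)
  set.seed(606)
  h2 <- draw_hyper(cfg, prior)
  expect_identical(h1, h2)
  expect_equal(length(unique(h1$tau)), h1$psi)
  s <- hyper_summaries(h1$tau)
  expect_identical(s$omega == 0, h1$psi == 1L)
  expect_true(all(h1$taxa$tau_b1 <= h1$taxa$tau))
})

test_that("hyper summaries follow the population-variance convention", {
  expect_equal(hyper_summaries(c(0.5, 0.5, 0.5)),
               tibble::tibble(e_tau = 0.5, omega = 0, psi = 1L),
               ignore_attr = TRUE)
  s <- hyper_summaries(c(1, 2, 3))
  expect_equal(s$e_tau, 2)
  expect_equal(s$omega, (2 / 3) / 2)
  expect_equal(s$psi, 3L)
  s2 <- hyper_summaries(c(1, 1, 4))
  expect_equal(s2$e_tau, 2)
  expect_equal(s2$omega, 1)
  expect_equal(s2$psi, 2L)
  expect_equal(hyper_summaries(c(0, 0))$omega, 0)
})
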