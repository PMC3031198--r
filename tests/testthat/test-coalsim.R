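test_that("pairwise coalescence times match the unstructured oracle", {
  # constant-size single population at the reference size: T2 ~ Exp(1)
  set.seed(21)
  prm <- const_pop_params(0.01)
  t2 <- replicate(3000, genealogy_tmrca(simulate_genealogy(prm, 1, 1)))
  expect_lt(abs(mean(t2) - 1), 3 * sd(t2) / sqrt(length(t2)))
  ks <- stats::ks.test(t2, stats::rexp(3000))
  expect_gt(ks$p.value, 0.001)
})

test_that("isolation forbids cross-population coalescence before tau", {
  set.seed(22)
  prm <- tibble::tibble(theta_a = 0.01, theta_a1 = 0.004, theta_a2 = 0.004,
                        theta_b1 = 0.005, theta_b2 = 0.005,
                        tau_b1 = 1, tau_b2 = 1, tau = 2, nm = 0)
  mins <- replicate(1e4, cross_coalescence_time(simulate_genealogy(prm, 1, 1)))
  expect_true(all(mins >= 2))
  # deep cross coalescence beyond tau follows tau + Exp(theta_ref/theta_a)
  extra <- mins - 2
  rate <- 0.01 / 0.01
  ks <- stats::ks.test(extra, stats::rexp(1e4, rate))
  expect_gt(ks$p.value, 0.001)
})

test_that("strong symmetric migration approaches the panmictic limit", {
  set.seed(23)
  prm <- tibble::tibble(theta_a = 0.01, theta_a1 = 0.005, theta_a2 = 0.005,
                        theta_b1 = 0.005, theta_b2 = 0.005,
                        tau_b1 = 0, tau_b2 = 0, tau = 50, nm = 100)
  t2 <- replicate(3000, genealogy_tmrca(simulate_genealogy(prm, 1, 1)))
  pan <- replicate(3000, genealogy_tmrca(simulate_genealogy(const_pop_params(0.01), 1, 1)))
  ks <- stats::ks.test(t2, pan)
  expect_gt(ks$p.value, 0.001)
})

test_that("zero mutation rate reproduces the root sequence everywhere", {
  set.seed(24)
  g <- simulate_genealogy(const_pop_params(0.01), 3, 3)
  aln <- mutate_sequences(g, 200, theta_site = 0)
  expect_equal(length(unique(aln$seqs)), 1)
})

test_that("Jukes-Cantor divergence matches the closed form", {
  set.seed(25)
  b <- 1  # total path length between the two leaves
  g <- structure(list(parent = c(3L, 3L, NA), time = c(0, 0, b / 2),
                      ntip = 2L, pops = c(1L, 2L)), class = "genealogy")
  mu <- 1  # per-site event rate theta_eff / 2 = 1
  aln <- mutate_sequences(g, 1e5, theta_site = 2, model = "JC")
  p_hat <- ham(aln$seqs[1], aln$seqs[2]) / 1e5
  p_exp <- 0.75 * (1 - exp(-4 / 3 * mu * b))
  se <- sqrt(p_exp * (1 - p_exp) / 1e5)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("expected pairwise differences scale linearly with the inheritance scalar", {
  set.seed(26)
  prm <- const_pop_params(0.01)
  mean_pi <- function(inh) {
    mean(replicate(4000, {
      g <- simulate_genealogy(prm, 1, 1)
      aln <- mutate_sequences(g, 500, theta_site = 0.01, inherit = inh)
      ham(aln$seqs[1], aln$seqs[2])
    }))
  }
  m1 <- mean_pi(1)
  m025 <- mean_pi(0.25)
  expect_lt(abs(m025 / m1 - 0.25), 0.05)
})

test_that("single-population E[pi per site] equals theta (unit calibration)", {
  set.seed(27)
  theta <- 0.005
  cfg <- sampling_config(config_template(1, 1, n1 = 1, n2 = 1, L = 1000))
  prior <- prior_spec(tau_range = c(0, 0), theta_a_range = c(theta, theta),
                      theta_b_range = c(theta / 2, theta / 2),
                      size_frac_range = c(1, 1), time_frac_range = c(0, 0),
                      rate_het = FALSE)
  rt <- simulate_reference_table(cfg, prior, 3e4, classes = "pi_b")
  pi_site <- rt$ss_pi_b.y1.m1 / 1000
  se <- sd(pi_site) / sqrt(length(pi_site))
  expect_lt(abs(mean(pi_site) - theta), 3 * se)
})

test_that("expected between-population divergence increases with tau", {
  set.seed(28)
  cfg <- sampling_config(config_template(1, 1, n1 = 2, n2 = 2, L = 500))
  mean_pib <- vapply(c(0.5, 2, 4), function(tau) {
    prior <- prior_spec(tau_range = c(tau, tau),
                        theta_a_range = c(0.005, 0.005),
                        theta_b_range = c(0.0025, 0.0025),
                        size_frac_range = c(1, 1), time_frac_range = c(0, 0),
                        rate_het = FALSE)
    mean(simulate_reference_table(cfg, prior, 4000,
                                  classes = "pi_b")$ss_pi_b.y1.m1)
  }, numeric(1))
  expect_true(all(diff(mean_pib) > 0))
})

test_that("simulated data sets match the sampling configuration exactly", {
  cfg <- sampling_config(config_template(3, c(2, 1, 3), n1 = c(2, 1, 3),
                                         n2 = c(2, 1, 2), L = c(80)))
  prior <- prior_spec(psi_fixed = 1)
  set.seed(29)
  hyper <- draw_hyper(cfg, prior)
  ds <- simulate_dataset(hyper, cfg)
  expect_equal(nrow(ds), nrow(cfg))
  for (i in seq_len(nrow(ds))) {
    aln <- ds$alignment[[i]]
    expect_equal(sum(aln$pops == 1), cfg$n1[i])
    expect_equal(sum(aln$pops == 2), cfg$n2[i])
    expect_equal(nchar(aln$seqs[1]), cfg$L[i])
  }
  # Psi = 1: all pairs simulated with the same tau
  expect_equal(length(unique(hyper$tau)), 1)
})

test_that("genealogies convert to valid ultrametric phylo trees", {
  skip_if_not_installed("ape")
  set.seed(30)
  g <- simulate_genealogy(const_pop_params(0.01), 4, 3)
  ph <- as_phylo_genealogy(g)
  expect_s3_class(ph, "phylo")
  expect_equal(ape::Ntip(ph), 7)
  depths <- ape::node.depth.edgelength(ph)
  expect_true(max(abs(depths[1:7] - max(depths[1:7]))) < 1e-9)
  expect_equal(max(depths), genealogy_tmrca(g), tolerance = 1e-12)
})
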