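small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_marine = 120, n_freshwater = 30, n_fw_demes = 3,
                   n_loci = 40, burn_in = 5, founder_n = 30,
                   sample_gens = c(2L, 3L))
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("initialization fixes alleles as specified", {
  cfg <- small_cfg()
  st <- initialize_sim(cfg)
  expect_equal(sum(st$demes$marine$h1) + sum(st$demes$marine$h2), 0)
  expect_true(all(st$demes$fw1$h1 == 1L & st$demes$fw1$h2 == 1L))
  expect_equal(sum(st$demes$fw2$h1) + sum(st$demes$fw2$h2), 0)
  # total freshwater alleles in the system: 2 N_f L in the seeded deme
  tot <- sum(vapply(st$demes, function(d) sum(d$h1) + sum(d$h2), numeric(1)))
  expect_equal(tot, 2 * cfg$n_freshwater * cfg$n_loci)
})

test_that("deme sizes stay constant and closed demes conserve absence", {
  cfg <- small_cfg()
  set.seed(101)
  st <- initialize_sim(cfg)
  for (i in 1:4) st <- step_generation(st, cfg)
  expect_equal(ncol(st$demes$marine$h1), cfg$n_marine)
  for (k in 1:3) expect_equal(ncol(st$demes[[paste0("fw", k)]]$h1),
                              cfg$n_freshwater)
  # zero migration: the marine deme can never acquire freshwater alleles
  cfg0 <- small_cfg(m_an_to_fw = 0, m_fw_to_an = 0)
  set.seed(102)
  st0 <- initialize_sim(cfg0)
  for (i in 1:6) st0 <- step_generation(st0, cfg0)
  expect_equal(sum(st0$demes$marine$h1) + sum(st0$demes$marine$h2), 0)
  # and the seeded deme stays fixed (no variation to lose)
  expect_true(all(st0$demes$fw1$h1 == 1L))
})

test_that("freshwater demes never exchange migrants directly", {
  # marine kept empty of freshwater alleles by construction: if fw demes
  # exchanged directly, fw1's fixed alleles could only appear in fw2/fw3
  # through that forbidden path within one generation
  cfg <- small_cfg(m_an_to_fw = 1, m_fw_to_an = 0)
  set.seed(103)
  st <- initialize_sim(cfg)
  st <- step_generation(st, cfg)
  expect_equal(sum(st$demes$fw2$h1) + sum(st$demes$fw2$h2), 0)
  expect_equal(sum(st$demes$fw3$h1) + sum(st$demes$fw3$h2), 0)
})

test_that("neutral allele frequencies are a martingale", {
  cfg <- sim_config(n_marine = 2, n_freshwater = 200, n_fw_demes = 1,
                    n_loci = 50, m_an_to_fw = 0, m_fw_to_an = 0,
                    s_fw = 0, s_marine = 0, burn_in = 1, founder_n = 2)
  set.seed(104)
  st <- initialize_sim(cfg)
  # start every locus at frequency 1/2, alternating haplotypes
  st$demes$fw1$h1[] <- 1L
  st$demes$fw1$h2[] <- 0L
  for (i in 1:15) st <- step_generation(st, cfg)
  freqs <- deme_allele_counts(st$demes$fw1) / (2 * cfg$n_freshwater)
  # mean over 50 loci stays within 3 SE of 1/2 (drift variance after t
  # generations is p q (1 - (1 - 1/2N)^t) per locus)
  v <- 0.25 * (1 - (1 - 1 / 400)^15)
  expect_lt(abs(mean(freqs) - 0.5), 3 * sqrt(v / 50))
})

test_that("one-generation selection matches the deterministic recursion", {
  N <- 8000
  cfg <- sim_config(n_marine = 2, n_freshwater = N, n_fw_demes = 1,
                    n_loci = 2, m_an_to_fw = 0, m_fw_to_an = 0,
                    s_fw = 0.1, s_marine = 0, burn_in = 1, founder_n = 2)
  set.seed(105)
  st <- initialize_sim(cfg)
  p0 <- 0.3
  hap <- matrix(0L, 2, 2 * N)
  hap[1, sample.int(2 * N, round(p0 * 2 * N))] <- 1L
  st$demes$fw1$h1 <- hap[, 1:N, drop = FALSE]
  st$demes$fw1$h2 <- hap[, N + 1:N, drop = FALSE]
  st <- step_generation(st, cfg)
  p1 <- mean(c(st$demes$fw1$h1[1, ], st$demes$fw1$h2[1, ]))
  s <- 0.1; h <- 0.5; q <- 1 - p0
  wbar <- p0^2 * (1 + s) + 2 * p0 * q * (1 + h * s) + q^2
  p_exp <- (p0^2 * (1 + s) + p0 * q * (1 + h * s)) / wbar
  expect_lt(abs(p1 - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / (2 * N)))
})

test_that("runs are reproducible from the seed", {
  cfg <- small_cfg()
  s1 <- run_burn_in(cfg, seed = 7)
  s2 <- run_burn_in(cfg, seed = 7)
  expect_identical(s1$demes, s2$demes)
  set.seed(3); fA1 <- found_lake(s1, cfg, "A")
  set.seed(3); fA2 <- found_lake(s2, cfg, "A")
  expect_identical(fA1$per_founder_fw, fA2$per_founder_fw)
  set.seed(4); t1 <- run_lake(fA1, cfg)
  set.seed(4); t2 <- run_lake(fA2, cfg)
  expect_identical(t1, t2)
})

test_that("founding scenarios enforce their constraints", {
  cfg <- small_cfg(burn_in = 3)
  st <- run_burn_in(cfg, seed = 9)
  # plant jackpots in the marine deme by hand
  st$demes$marine$h1[, 1:5] <- 1L
  set.seed(10)
  fB <- found_lake(st, cfg, "B")
  expect_true(all(fB$contents < cfg$jackpot_threshold))
  expect_equal(fB$founder_jackpots, 0)
  # infeasible scenario B errors
  st$demes$marine$h1[] <- 1L
  expect_error(found_lake(st, cfg, "B"), "infeasible")
  # founders without freshwater alleles keep the lake at zero forever
  st0 <- initialize_sim(cfg)
  f0 <- list(deme = list(h1 = st0$demes$marine$h1[, 1:30],
                         h2 = st0$demes$marine$h2[, 1:30],
                         env = "freshwater"))
  set.seed(11)
  tr <- run_lake(f0, cfg)
  expect_true(all(tr$mean_content == 0))
})

test_that("raising the freshwater advantage cannot lower lake content", {
  cfg <- small_cfg(n_loci = 30, burn_in = 2, sample_gens = c(2L, 6L, 9L))
  st <- run_burn_in(cfg, seed = 12)
  st$demes$marine$h1[, 1:12] <- 1L  # ensure raw material is present
  set.seed(13); f <- found_lake(st, cfg, "A")
  res <- vapply(c(0, 0.01, 0.1, 0.4), function(s_fw) {
    cfg2 <- cfg; cfg2$s_fw <- s_fw
    set.seed(14)
    tail(run_lake(f, cfg2)$mean_content, 1)
  }, numeric(1))
  expect_true(all(diff(res) >= -0.02))
  expect_gt(res[4], res[1])
})

test_that("scenario comparison reduces to the empirical KS statistic", {
  same <- list(
    founders = data.frame(replicate = rep(1:4, 2),
                          scenario = rep(c("A", "B"), each = 4),
                          total_fw = rep(c(5, 6, 7, 8), 2),
                          jackpots = 0),
    trajectories = data.frame(replicate = rep(1:4, 2),
                              scenario = rep(c("A", "B"), each = 4),
                              generation = 2L,
                              mean_content = 0.1, min_content = 0.1,
                              max_content = 0.1))
  cs <- compare_scenarios(same)
  expect_equal(cs$ks_statistic, 0)
  disj <- same
  disj$founders$total_fw[5:8] <- 100:103
  expect_equal(compare_scenarios(disj)$ks_statistic, 1)
  # brute-force sup-difference of empirical CDFs
  set.seed(15)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  brute <- max(vapply(sort(c(a, b)), function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
  two <- same
  two$founders <- data.frame(replicate = c(seq_along(a), seq_along(b)),
                             scenario = rep(c("A", "B"), c(40, 35)),
                             total_fw = c(a, b), jackpots = 0)
  expect_equal(compare_scenarios(two)$ks_statistic, brute)
})

test_that("the neutral stationary deme is seed-stable with a live spectrum", {
  d1 <- neutral_stationary_deme(30, 400, 0.3, generations = 60, seed = 21)
  d2 <- neutral_stationary_deme(30, 400, 0.3, generations = 60, seed = 21)
  expect_identical(d1, d2)
  k <- deme_allele_counts(d1)
  expect_true(any(k > 0 & k < 60))
  expect_true(all(k < 60))  # fixed sites recycled
})
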