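#' Forward Wright-Fisher simulation of the transporter process
#'
#' A large oceanic (anadromous) deme exchanges migrants with 10 freshwater
#' demes (no freshwater-freshwater exchange). All 341 adaptive loci start
#' fixed for the freshwater allele in one freshwater deme and for the
#' oceanic allele everywhere else; there is no de novo mutation. Selection
#' is environment-dependent and multiplicative across loci (per-locus
#' fitness 1, 1 + h s, 1 + s for freshwater dosage 0/1/2, with s > 0 in
#' freshwater and s < 0 in the ocean). Generations are non-overlapping:
#' each offspring draws its parents' deme by the backward migration rates,
#' then two parents fitness-proportionally from that deme, and one
#' recombinant gamete per parent (Poisson crossovers on the genetic map).
#' After a burn-in that lets the metapopulation reach migration-selection
#' balance, a new lake is founded by sampling founders from the marine deme
#' -- either unconditionally (scenario A) or excluding jackpot carriers
#' (scenario B) -- and run in isolation.
#'
#' @name transporter
NULL

#' Simulation configuration
#'
#' @param n_marine marine deme size (default 2000).
#' @param n_freshwater size of each freshwater deme (default 500).
#' @param n_fw_demes number of freshwater demes (default 10).
#' @param n_loci number of adaptive loci (default 341).
#' @param m_an_to_fw backward migration rate into each freshwater deme from
#'   the marine deme (default 0.001).
#' @param m_fw_to_an backward migration rate into the marine deme from each
#'   freshwater deme (default 0.01 per deme, the per-source-population
#'   convention of forward simulators).
#' @param s_fw selection coefficient per freshwater allele pair in
#'   freshwater demes (default 0.01).
#' @param s_marine selection coefficient in the marine deme (default -0.01).
#' @param h dominance of the freshwater allele (default 0.5).
#' @param burn_in burn-in generations (default 1000).
#' @param founder_n lake founders (default `min(3000, 0.3 * n_marine)`).
#' @param lake_n lake deme size after founding (default `founder_n`).
#' @param sample_gens lake generations at which content is recorded
#'   (default c(2, 3, 4, 6, 9), the sampled years after founding).
#' @param jackpot_threshold content defining a jackpot carrier (default
#'   0.05).
#' @param panel optional `locus_panel` supplying the genetic map; by default
#'   a 344-locus panel is generated and truncated to `n_loci`.
#' @param suppress_het_recombination if TRUE, recombination between
#'   consecutive loci is suppressed in individuals heterozygous at both
#'   flanking loci (default FALSE).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_marine = 2000L, n_freshwater = 500L,
                       n_fw_demes = 10L, n_loci = 341L,
                       m_an_to_fw = 0.001, m_fw_to_an = 0.01,
                       s_fw = 0.01, s_marine = -0.01, h = 0.5,
                       burn_in = 1000L,
                       founder_n = NULL, lake_n = NULL,
                       sample_gens = c(2L, 3L, 4L, 6L, 9L),
                       jackpot_threshold = 0.05,
                       panel = NULL,
                       suppress_het_recombination = FALSE) {
  if (is.null(founder_n)) founder_n <- as.integer(min(3000, 0.3 * n_marine))
  if (is.null(lake_n)) lake_n <- founder_n
  stopifnot(n_marine >= 2, n_freshwater >= 2, n_fw_demes >= 1, n_loci >= 1,
            m_an_to_fw >= 0, m_an_to_fw <= 1,
            m_fw_to_an >= 0, m_fw_to_an <= 1,
            burn_in >= 1, founder_n >= 2, founder_n <= n_marine,
            s_fw > -1, s_marine > -1, jackpot_threshold > 0)
  if (is.null(panel)) {
    panel <- generate_locus_panel(n_loci = max(n_loci, 2L), seed = 99L)
  }
  if (nrow(panel$loci) < n_loci) stop("panel has fewer loci than n_loci")
  rec <- recombination_fractions(panel)[seq_len(n_loci - 1)]
  structure(list(n_marine = as.integer(n_marine),
                 n_freshwater = as.integer(n_freshwater),
                 n_fw_demes = as.integer(n_fw_demes),
                 n_loci = as.integer(n_loci),
                 m_an_to_fw = m_an_to_fw, m_fw_to_an = m_fw_to_an,
                 s_fw = s_fw, s_marine = s_marine, h = h,
                 burn_in = as.integer(burn_in),
                 founder_n = as.integer(founder_n),
                 lake_n = as.integer(lake_n),
                 sample_gens = as.integer(sample_gens),
                 jackpot_threshold = jackpot_threshold,
                 rec = rec,
                 suppress_het_recombination = suppress_het_recombination),
            class = "sim_config")
}

# a deme is a pair of L x n 0/1 haplotype matrices (one column per
# individual, so gamete walks are contiguous) plus an environment label
new_deme <- function(n, L, fill = 0L, env = "marine") {
  list(h1 = matrix(as.integer(fill), L, n),
       h2 = matrix(as.integer(fill), L, n), env = env)
}

deme_size <- function(deme) ncol(deme$h1)

deme_content <- function(deme) {
  cpp_allele_counts(deme$h1, deme$h2) / (2 * nrow(deme$h1))
}

#' Initialize the metapopulation
#'
#' Marine deme and all but one freshwater deme fixed for oceanic alleles;
#' freshwater deme 1 fixed for freshwater alleles at every locus.
#'
#' @param config a `sim_config`.
#' @return a `sim_state`: list of demes (`marine`, `fw1`..`fwK`) and a
#'   generation counter.
#' @export
initialize_sim <- function(config) {
  L <- config$n_loci
  demes <- c(list(marine = new_deme(config$n_marine, L, 0L, "marine")),
             stats::setNames(
               lapply(seq_len(config$n_fw_demes), function(i) {
                 new_deme(config$n_freshwater, L,
                          fill = if (i == 1L) 1L else 0L, env = "freshwater")
               }),
               paste0("fw", seq_len(config$n_fw_demes))))
  structure(list(demes = demes, generation = 0L, config = config),
            class = "sim_state")
}

# log-fitness of every individual in a deme under its environment
deme_log_fitness <- function(deme, config) {
  s <- if (deme$env == "freshwater") config$s_fw else config$s_marine
  if (s == 0) return(rep(0, ncol(deme$h1)))
  hh <- cpp_het_hom(deme$h1, deme$h2)
  hh[, 1] * log(1 + config$h * s) + hh[, 2] * log(1 + s)
}

# produce `n_off` offspring whose parents come from `src` deme
reproduce_from <- function(src, n_off, config, w = NULL) {
  if (is.null(w)) w <- exp(deme_log_fitness(src, config))
  parents <- sample.int(ncol(src$h1), 2L * n_off, replace = TRUE, prob = w)
  g <- cpp_make_gametes(src$h1, src$h2, parents, config$rec)
  list(h1 = g[, seq_len(n_off), drop = FALSE],
       h2 = g[, n_off + seq_len(n_off), drop = FALSE])
}

#' Advance the metapopulation one generation
#'
#' @param state a `sim_state`.
#' @param config a `sim_config` (defaults to the state's own).
#' @return the updated `sim_state`.
#' @export
step_generation <- function(state, config = state$config) {
  demes <- state$demes
  K <- config$n_fw_demes
  # fitness computed once per source deme
  w <- lapply(demes, deme_log_fitness, config = config)
  w <- lapply(w, function(lw) exp(lw - max(lw)))
  new_demes <- demes

  # marine deme: sources are marine plus each freshwater deme (rate per
  # source deme)
  src_probs <- c(1 - K * config$m_fw_to_an, rep(config$m_fw_to_an, K))
  if (src_probs[1] < 0)
    stop("n_fw_demes * m_fw_to_an must not exceed 1")
  n_by_src <- as.integer(stats::rmultinom(1, config$n_marine, src_probs))
  parts <- list()
  for (d in seq_along(n_by_src)) {
    if (n_by_src[d] == 0) next
    parts[[length(parts) + 1L]] <-
      reproduce_from(demes[[d]], n_by_src[d], config, w[[d]])
  }
  new_demes$marine$h1 <- do.call(cbind, lapply(parts, `[[`, "h1"))
  new_demes$marine$h2 <- do.call(cbind, lapply(parts, `[[`, "h2"))

  # each freshwater deme: sources are itself and the marine deme; no
  # freshwater-freshwater exchange
  for (i in seq_len(K)) {
    nm <- paste0("fw", i)
    n_mig <- stats::rbinom(1, config$n_freshwater, config$m_an_to_fw)
    own <- reproduce_from(demes[[nm]], config$n_freshwater - n_mig, config,
                          w[[nm]])
    if (n_mig > 0) {
      mig <- reproduce_from(demes$marine, n_mig, config, w$marine)
      new_demes[[nm]]$h1 <- cbind(own$h1, mig$h1)
      new_demes[[nm]]$h2 <- cbind(own$h2, mig$h2)
    } else {
      new_demes[[nm]]$h1 <- own$h1
      new_demes[[nm]]$h2 <- own$h2
    }
  }
  state$demes <- new_demes
  state$generation <- state$generation + 1L
  state
}

#' Run the burn-in to migration-selection balance
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @param checkpoint_every record the marine content distribution every this
#'   many generations (0 = never).
#' @return the `sim_state` at generation `config$burn_in`, with a
#'   `checkpoints` element (data.frame generation/mean/median/max marine
#'   content) when checkpoints were requested.
#' @export
run_burn_in <- function(config, seed = 1L, checkpoint_every = 0L) {
  set.seed(seed)
  state <- initialize_sim(config)
  cps <- list()
  for (g in seq_len(config$burn_in)) {
    state <- step_generation(state, config)
    if (checkpoint_every > 0 && g %% checkpoint_every == 0) {
      ct <- deme_content(state$demes$marine)
      cps[[length(cps) + 1L]] <- data.frame(
        generation = g, mean = mean(ct), median = stats::median(ct),
        max = max(ct),
        frac_jackpot = mean(ct >= config$jackpot_threshold))
    }
  }
  state$checkpoints <- if (length(cps)) do.call(rbind, cps) else NULL
  state
}

#' Found the lake population
#'
#' Scenario A samples `founder_n` marine individuals uniformly; scenario B
#' samples uniformly from the marine individuals whose freshwater content is
#' below the jackpot threshold. No migration occurs after founding.
#'
#' @param state burned-in `sim_state`.
#' @param config a `sim_config`.
#' @param scenario "A" or "B".
#' @return list: `deme` (the founder deme, freshwater environment),
#'   `founder_total_fw` (total freshwater alleles across founders),
#'   `founder_jackpots` (count), `contents` (per founder).
#' @export
found_lake <- function(state, config = state$config, scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  marine <- state$demes$marine
  ct <- deme_content(marine)
  pool <- if (scenario == "A") seq_along(ct)
          else which(ct < config$jackpot_threshold)
  if (length(pool) < config$founder_n)
    stop("scenario ", scenario, " infeasible: only ", length(pool),
         " eligible marine individuals for ", config$founder_n, " founders")
  idx <- sample(pool, config$founder_n)
  deme <- list(h1 = marine$h1[, idx, drop = FALSE],
               h2 = marine$h2[, idx, drop = FALSE], env = "freshwater")
  list(deme = deme,
       founder_total_fw = sum(deme$h1) + sum(deme$h2),
       founder_jackpots = sum(ct[idx] >= config$jackpot_threshold),
       contents = ct[idx],
       per_founder_fw = cpp_allele_counts(deme$h1, deme$h2))
}

#' Run the founded lake forward
#'
#' Isolated Wright-Fisher deme of size `config$lake_n` in the freshwater
#' environment; per-individual content is summarized at the sampled
#' generations.
#'
#' @param founders result of [found_lake()].
#' @param config a `sim_config`.
#' @return data.frame per sampled generation: generation, mean_content,
#'   min_content, max_content.
#' @export
run_lake <- function(founders, config) {
  deme <- founders$deme
  rows <- list()
  gmax <- max(config$sample_gens)
  for (g in seq_len(gmax)) {
    off <- reproduce_from(deme, config$lake_n, config)
    deme <- list(h1 = off$h1, h2 = off$h2, env = "freshwater")
    if (g %in% config$sample_gens) {
      ct <- deme_content(deme)
      rows[[length(rows) + 1L]] <- data.frame(
        generation = g, mean_content = mean(ct), min_content = min(ct),
        max_content = max(ct))
    }
  }
  do.call(rbind, rows)
}

#' Run replicated founding scenarios from shared burn-ins
#'
#' For each replicate: one burn-in, then a scenario-A and a scenario-B
#' founding and lake run from the same equilibrium state.
#'
#' @param config a `sim_config`.
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @return list: `trajectories` (data.frame replicate/scenario/generation/
#'   mean/min/max content), `founders` (data.frame replicate/scenario/
#'   total_fw/jackpots).
#' @export
run_transporter_scenarios <- function(config, replicates = 20L, seed = 1L) {
  traj <- list(); fdr <- list()
  for (r in seq_len(replicates)) {
    state <- run_burn_in(config, seed = seed + r)
    per_founder <- list()
    for (sc in c("A", "B")) {
      f <- found_lake(state, config, sc)
      per_founder[[sc]] <- f$per_founder_fw
      tt <- run_lake(f, config)
      tt$replicate <- r; tt$scenario <- sc
      traj[[length(traj) + 1L]] <- tt
      fdr[[length(fdr) + 1L]] <- data.frame(
        replicate = r, scenario = sc, total_fw = f$founder_total_fw,
        jackpots = f$founder_jackpots)
    }
    # within-replicate comparability of the founding allele pools
    ks <- suppressWarnings(stats::ks.test(per_founder$A, per_founder$B))
    i <- length(fdr) - 1:0
    fdr[[i[1]]]$founder_ks_p <- fdr[[i[2]]]$founder_ks_p <- ks$p.value
  }
  list(trajectories = do.call(rbind, traj), founders = do.call(rbind, fdr))
}

#' Compare founding scenarios
#'
#' Two-sample Kolmogorov-Smirnov test on founder total freshwater alleles,
#' and per-generation mean and min-max envelopes per scenario.
#'
#' @param result output of [run_transporter_scenarios()], or a list with
#'   `trajectories` and `founders` shaped the same way.
#' @return list: `ks_statistic`, `ks_p`, `envelopes` (data.frame scenario/
#'   generation/mean/min/max of replicate mean contents).
#' @export
compare_scenarios <- function(result) {
  f <- result$founders
  a <- f$total_fw[f$scenario == "A"]
  b <- f$total_fw[f$scenario == "B"]
  ks <- suppressWarnings(stats::ks.test(a, b))
  tr <- result$trajectories
  env <- do.call(rbind, lapply(split(tr, list(tr$scenario, tr$generation)),
    function(d) data.frame(scenario = d$scenario[1],
                           generation = d$generation[1],
                           mean = mean(d$mean_content),
                           min = min(d$mean_content),
                           max = max(d$mean_content))))
  rownames(env) <- NULL
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       envelopes = env[order(env$scenario, env$generation), ])
}

#' Neutral single-deme Wright-Fisher run at mutation-drift stationarity
#'
#' The adaptive simulator itself has no de novo mutation, so neutral
#' stationarity is provided by a dedicated single-deme run over a pool of
#' unlinked sites: the spectrum is initialized at the neutral equilibrium
#' shape (per-site allele-count mass proportional to 1/k), and each
#' generation of drift (s = 0, through the same meiosis engine) is followed
#' by Poisson mutation influx -- new singletons placed at currently
#' monomorphic sites, with sites fixed for the derived allele recycled as
#' substitutions. After the burn-in window the spectrum is a neutral
#' stationary sample on which Tajima's D is centered near zero.
#'
#' @param n_diploid deme size N.
#' @param n_loci_pool number of sites carried (must comfortably exceed the
#'   expected number of segregating sites, about theta * a_{2N-1} with
#'   theta = 4 N u).
#' @param u_genome expected new mutations per haploid genome per generation.
#' @param generations generations to run (a few N suffices from the 1/k
#'   start; default `5 * n_diploid`).
#' @param seed integer seed.
#' @return the deme (h1/h2 matrices, loci x individuals).
#' @export
neutral_stationary_deme <- function(n_diploid, n_loci_pool = 1500L,
                                    u_genome = 0.5,
                                    generations = 5L * n_diploid,
                                    seed = 1L) {
  set.seed(seed)
  N2 <- 2L * n_diploid
  theta <- 2 * N2 * u_genome / 2  # 4 N u
  S0 <- min(n_loci_pool, round(theta * sum(1 / seq_len(N2 - 1L))))
  k <- sample.int(N2 - 1L, S0, replace = TRUE,
                  prob = 1 / seq_len(N2 - 1L))
  haps <- matrix(0L, n_loci_pool, N2)
  for (l in seq_len(S0)) haps[l, sample.int(N2, k[l])] <- 1L
  deme <- list(h1 = haps[, seq_len(n_diploid), drop = FALSE],
               h2 = haps[, n_diploid + seq_len(n_diploid), drop = FALSE],
               env = "freshwater")
  # lightweight neutral config: unlinked sites, no selection
  cfg <- list(rec = rep(0.5, max(n_loci_pool - 1L, 0L)),
              s_fw = 0, s_marine = 0, h = 0.5)
  for (g in seq_len(generations)) {
    off <- reproduce_from(deme, n_diploid, cfg)
    deme <- list(h1 = off$h1, h2 = off$h2, env = "freshwater")
    cnt <- rowSums(deme$h1) + rowSums(deme$h2)
    fixed <- cnt == N2
    if (any(fixed)) {
      deme$h1[fixed, ] <- 0L
      deme$h2[fixed, ] <- 0L
      cnt[fixed] <- 0L
    }
    n_mut <- stats::rpois(1, N2 * u_genome)
    free <- which(cnt == 0L)
    if (n_mut > 0 && length(free) > 0) {
      loc <- if (length(free) == 1L) free
             else sample(free, min(n_mut, length(free)))
      for (l in loc) {
        i <- sample.int(N2, 1L)
        if (i <= n_diploid) deme$h1[l, i] <- 1L
        else deme$h2[l, i - n_diploid] <- 1L
      }
    }
  }
  deme
}

#' Allele counts of a deme
#'
#' @param deme a deme (h1/h2, loci x individuals).
#' @return integer vector of freshwater-allele counts per locus (out of 2N).
#' @export
deme_allele_counts <- function(deme) {
  rowSums(deme$h1) + rowSums(deme$h2)
}
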