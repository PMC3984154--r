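# Fixtures are generated in code at test time; nothing is stored on disk.

# 2-site, 2-species, 2-visit long-format counts file (values by site-major,
# then visit, then species): sp1/sp2 counts per (site, visit) row.
write_toy_long <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  counts <- file.path(dir, "counts.csv")
  writeLines(c("site,visit,species,count",
               "A,1,sp1,0", "A,1,sp2,1",
               "A,2,sp1,2", "A,2,sp2,3",
               "B,1,sp1,1", "B,1,sp2,0",
               "B,2,sp1,0", "B,2,sp2,1"), counts)
  covs <- file.path(dir, "covs.csv")
  writeLines(c("site,forest_ha,elev", "A,120.5,10", "B,300.25,35"), covs)
  list(counts = counts, covs = covs, dir = dir)
}

write_toy_meta <- function(dir = tempfile(),
                           species = c("sp2", "sp3", "sp1"),
                           guild = c("A", "B", "A")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "meta.csv")
  df <- data.frame(species = species,
                   mass = c(10, 20, 30), beak = c(1.5, 2.5, 3.5),
                   tarsus = c(2, 3, 4), wing = c(7, 9, 11),
                   tail = c(5, 6, 8),
                   guild = guild,
                   sound_mw = c(0.4, 1.2, 2.2))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# short-chain fit used across MCMC tests
quick_fit <- function(sim, mode = "full", n_iter = 2500, n_burn = 1000,
                      thin = 2, seed = 11, ...) {
  fit_msnmix(sim$data, sim$meta, mode = mode,
             site_transform = "none", detect_transform = "none",
             control = mcmc_control(n_chains = 1, n_iter = n_iter,
                                    n_burn = n_burn, thin = thin, seed = seed),
             ...)
}

# independent brute-force pmf of N | y (direct density products, truncated
# far in the tail) -- used as an oracle for the sampler's conditional
enum_latent_pmf <- function(y, lambda, p, upper = 400) {
  Ns <- max(y):upper
  w <- dpois(Ns, lambda) *
    vapply(Ns, function(Nv) prod(dbinom(y, Nv, p)), numeric(1))
  data.frame(N = Ns, prob = w / sum(w))
}
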