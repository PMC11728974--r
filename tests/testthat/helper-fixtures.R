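# Deterministic parameter vector covering the full registry, with overrides.
make_params <- function(network, value = 0.1, ...) {
  reg <- param_registry(network)
  p <- stats::setNames(rep(value, nrow(reg)), reg$name)
  ov <- list(...)
  p[names(ov)] <- unlist(ov)
  p
}

# Flat input profiles (constant AA / omega-3), handy for analytic limits.
flat_profiles <- function(variant = "EPA", condition = "ctrl", AA = 0,
                          O3 = 0, ATP0 = 0, tmax = 60) {
  o3name <- if (variant == "DHA") "DHA" else "EPA"
  input_profiles(condition, c(0, tmax),
                 stats::setNames(list(c(AA, AA), c(O3, O3)), c("AA", o3name)),
                 ATP0 = ATP0)
}

# One seeded synthetic world (truth, profiles, datasets), cached per seed.
.fixture_cache <- new.env(parent = emptyenv())
get_world <- function(seed = 1, cv = 0.05) {
  key <- paste0("world_", seed, "_", cv)
  if (is.null(.fixture_cache[[key]])) {
    spec <- synthetic_spec(seed = seed, cv = cv)
    net <- build_network("EPA")
    truth <- gen_true_params(spec, net)
    profiles <- lapply(stats::setNames(spec$conditions, spec$conditions),
                       gen_substrate_profiles, spec = spec)
    datasets <- do.call(rbind, c(lapply(profiles, function(pr)
      gen_dataset(net, truth, pr, spec)), make.row.names = FALSE))
    .fixture_cache[[key]] <- list(spec = spec, net = net, truth = truth,
                                  profiles = profiles, datasets = datasets)
  }
  .fixture_cache[[key]]
}

# The full default-budget recovery experiment under the study conditions
# (seed 1, 5% CV, 3 replicates, default grid); shared by the acceptance
# tests, computed once.
get_recovery <- function() {
  if (is.null(.fixture_cache$recovery)) {
    .fixture_cache$recovery <- recovery_experiment(synthetic_spec(seed = 1),
                                                   fit_config())
  }
  .fixture_cache$recovery
}
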