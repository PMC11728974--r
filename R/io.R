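# Validate the tidy time-series schema shared by datasets and artifacts.
check_timeseries <- function(x) {
  required <- c("condition", "time_min", "species", "replicate", "value")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(x$value))) {
    stop("non-finite value at row ", which(!is.finite(x$value))[1])
  }
  if (any(x$value < 0)) {
    stop("negative value at row ", which(x$value < 0)[1])
  }
  key <- paste(x$condition, x$species, x$time_min, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (condition, species, time, replicate) at row ",
         which(duplicated(key))[1])
  }
  invisible(x)
}

#' Read a tidy time-series CSV
#'
#' Reads and validates replicate time-course measurements in the package's
#' tidy long format: columns `condition`, `time_min`, `species`, `replicate`,
#' `value` (pmol/ug DNA). Rows are sorted by condition, species, time and
#' replicate; replicate indices are renumbered contiguously from 1 within
#' each (condition, species) cell.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_timeseries <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_timeseries(x)
  x <- x[order(x$condition, x$species, x$time_min, x$replicate), ,
         drop = FALSE]
  key <- paste(x$condition, x$species, x$time_min, sep = "\r")
  x$replicate <- stats::ave(x$replicate, key, FUN = function(r) rank(r))
  rownames(x) <- NULL
  x
}

#' Write a tidy time-series CSV
#'
#' @param x Data frame in the tidy time-series schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  check_timeseries(x)
  # full double precision so the file round-trips bit-exactly
  x$value <- sprintf("%.17g", x$value)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical md5 of a run configuration (embedded in every artifact).
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

# Resolve a run configuration: a YAML path or a list; defaults filled in.
resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(variant = "EPA", conditions = c("ctrl", "EPA"),
                   alpha = 0.05, seed = 1, nr = 3, cv = 0.05,
                   budget = 2000, maxit = 100, penalty_weight = 1000,
                   bound = 10, metabolite = "PGD2",
                   kPGH2 = NULL, kPGH3 = NULL, data = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' Run one pipeline stage
#'
#' Programmatic command dispatcher behind the `cyberlipid` command line:
#' `synth` generates a synthetic study (truth, profiles, noisy datasets),
#' `simulate` integrates the true model, `fit` runs the two-stage estimation,
#' `validate` adds the lack-of-fit F-test report, `loo-cv` runs
#' leave-one-out-metabolite cross-validation, and `switch` evaluates the
#' activity-switch ratio and surface. Every artifact embeds the seed and a
#' hash of the resolved configuration; stochastic stages are reproducible
#' given (config, seed).
#'
#' @param name One of `"synth"`, `"simulate"`, `"fit"`, `"validate"`,
#'   `"loo-cv"`, `"switch"`.
#' @param config A configuration list or path to a YAML file; see
#'   `resolve_config` defaults (variant, conditions, seed, optimizer budget,
#'   penalty weight, bound, significance level, `kPGH2`/`kPGH3` for
#'   `switch`).
#' @param out Output directory (created if missing); `NULL` writes nothing.
#' @return Invisibly, a list with the stage results (also serialized to
#'   `<out>/<name>_results.json` plus CSV artifacts when `out` is given).
#' @export
run_command <- function(name, config = list(), out = NULL) {
  known <- c("synth", "simulate", "fit", "validate", "loo-cv", "switch")
  if (!(is.character(name) && length(name) == 1L && name %in% known)) {
    stop("unknown command: ", paste(name, collapse = ", "),
         " (usage: one of ", paste(known, collapse = ", "), ")")
  }
  config <- resolve_config(config)
  meta <- list(command = name, seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("cyberlipid")))
  res <- list(meta = meta)
  artifacts <- list()

  if (name == "switch") {
    k2 <- if (is.null(config$kPGH2)) 1 else config$kPGH2
    k3 <- if (is.null(config$kPGH3)) 2 else config$kPGH3
    grid <- seq(0, 50, length.out = 26)
    sa <- switch_surface(grid, grid, k2, k3)
    res$switch <- list(kPGH2 = k2, kPGH3 = k3, ratio = sa$ratio)
    artifacts$switch_surface <- data.frame(
      AA = rep(sa$AA, times = length(sa$EPA)),
      EPA = rep(sa$EPA, each = length(sa$AA)),
      vPGH2 = as.vector(sa$vPGH2), vPGH3 = as.vector(sa$vPGH3))
  } else {
    spec <- synthetic_spec(seed = config$seed, nr = config$nr,
                           cv = config$cv, conditions = config$conditions)
    network <- build_network(config$variant)
    truth <- gen_true_params(spec, network)
    profiles <- lapply(stats::setNames(spec$conditions, spec$conditions),
                       gen_substrate_profiles, spec = spec,
                       variant = config$variant)
    datasets <- if (!is.null(config$data)) read_timeseries(config$data) else
      do.call(rbind, c(lapply(profiles, function(pr)
        gen_dataset(network, truth, pr, spec)), make.row.names = FALSE))
    if (name == "synth") {
      res$truth <- as.list(truth)
      artifacts$dataset <- datasets
    } else if (name == "simulate") {
      trajs <- lapply(profiles, function(pr)
        as.data.frame(simulate_model(network, truth, pr)))
      artifacts$trajectories <- do.call(rbind, c(trajs,
                                                 make.row.names = FALSE))
      res$truth <- as.list(truth)
    } else {
      fcfg <- fit_config(budget = config$budget, maxit = config$maxit,
                         penalty_weight = config$penalty_weight,
                         bound = config$bound)
      rg <- truth_ranges(spec, network)
      fcfg$lower <- vapply(rg, `[`, numeric(1), 1)
      fcfg$upper <- vapply(rg, `[`, numeric(1), 2)
      if (name == "loo-cv") {
        cvres <- loo_metabolite_cv(datasets, network, profiles,
                                   config$metabolite, config = fcfg,
                                   seed = config$seed)
        fit <- cvres$fit
        res$loo <- list(metabolite = cvres$metabolite,
                        heldout_error = cvres$heldout_error,
                        fitted_errors = as.list(cvres$fitted_errors))
      } else {
        fit <- fit_model(datasets, network, profiles, config = fcfg,
                         seed = config$seed)
      }
      res$parameters <- as.list(fit$params)
      res$X0 <- as.list(fit$params[grep("^x0", names(fit$params))])
      res$cost <- fit$cost
      res$penalty <- fit$penalty
      res$intermediate_max <- as.list(fit$intermediate_max)
      artifacts$fitted_trajectories <- fit$trajectories
      if (name == "validate") {
        rep <- f_test_report(fit, datasets, alpha = config$alpha)
        res$f_test <- lapply(seq_len(nrow(rep)), function(i) as.list(rep[i, ]))
        artifacts$f_test <- as.data.frame(rep)
      }
    }
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, file.path(out, paste0(name, "_results.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(artifacts)) {
      utils::write.csv(artifacts[[nm]],
                       file.path(out, paste0(name, "_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(c(res, list(artifacts = artifacts)))
}
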