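#' Simulation configuration for the synthetic survey
#'
#' Describes a monthly multi-site zooplankton survey along a
#' mesotrophic-to-eutrophic gradient: 10 sites sampled for 12 months
#' (~118 samples after accidental losses), 46 taxa classified by the default
#' trait vocabulary, and composite trophic index targets spanning 45-65.
#' Species respond to the latent trophic score through Gaussian niches;
#' `filtering_strength` (kappa) scales the environmental filtering and
#' `dominance_concentration` (theta) sharpens the baseline rank-abundance
#' curve.
#'
#' @param n_sites,n_months,n_species survey dimensions.
#' @param trait_vocabulary modality mapping, default
#'   [default_trait_vocabulary()].
#' @param gradient_range low/high composite-index targets (0-100 scale).
#' @param filtering_strength kappa >= 0; 0 = neutral (no gradient effect).
#' @param dominance_concentration theta >= 0; lognormal sd of baseline
#'   abundances.
#' @param missing_sample_rate fraction of site-months lost (default 2/120).
#' @param env_noise_sd multiplicative (log-scale) noise sd on back-solved
#'   chemistry; the round-trip tolerance on recomputed TLIc is
#'   `10 * env_noise_sd` index units.
#' @param detection_limit abundances below this (ind/L) record as 0,
#'   emulating the counting protocol's detection floor.
#' @param tolerant_modalities trait modalities whose carriers get niche
#'   optima in the eutrophic range (default: the groups dominant in
#'   nutrient-rich water).
#' @param master_seed integer; all stages derive child seeds from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10L, n_months = 12L, n_species = 46L,
                       trait_vocabulary = default_trait_vocabulary(),
                       gradient_range = c(45, 65),
                       filtering_strength = 5,
                       dominance_concentration = 1,
                       missing_sample_rate = 2 / 120,
                       env_noise_sd = 0.05,
                       detection_limit = 0.3,
                       tolerant_modalities = c("filter_feeding", "malleate", "planktonic"),
                       master_seed = 1L) {
  if (!is_count(n_sites) || !is_count(n_months))
    rfd_stop("configuration_error", "n_sites and n_months must be positive integers")
  if (!is_count(n_species) || n_species < 4)
    rfd_stop("configuration_error", "n_species must be an integer >= 4")
  if (length(gradient_range) != 2L || gradient_range[1] > gradient_range[2])
    rfd_stop("configuration_error", "gradient_range must be (low, high) with low <= high")
  if (any(gradient_range <= 0) || any(gradient_range >= 100))
    rfd_stop("configuration_error", "gradient_range must lie inside (0, 100)")
  if (filtering_strength < 0 || dominance_concentration < 0)
    rfd_stop("configuration_error", "filtering_strength and dominance_concentration must be >= 0")
  if (missing_sample_rate < 0 || missing_sample_rate >= 1)
    rfd_stop("configuration_error", "missing_sample_rate must be in [0, 1)")
  if (any(lengths(trait_vocabulary) < 2L))
    rfd_stop("configuration_error", "every trait category needs >= 2 modalities")
  structure(list(n_sites = as.integer(n_sites), n_months = as.integer(n_months),
                 n_species = as.integer(n_species),
                 trait_vocabulary = trait_vocabulary,
                 gradient_range = as.numeric(gradient_range),
                 filtering_strength = filtering_strength,
                 dominance_concentration = dominance_concentration,
                 missing_sample_rate = missing_sample_rate,
                 env_noise_sd = env_noise_sd,
                 detection_limit = detection_limit,
                 tolerant_modalities = tolerant_modalities,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

#' Generate a random taxon-by-trait table
#'
#' Assigns each taxon one modality per category, independently across
#' categories. Whenever the number of taxa is at least the category's
#' modality count, every modality of that category is used at least once
#' (coverage is placed at random positions). Deterministic for a fixed seed.
#'
#' @param n_species number of taxa (>= 1).
#' @param vocabulary modality mapping; every category must be nonempty.
#' @param seed integer seed.
#' @return validated `trait_table` with taxa `taxon_01`, `taxon_02`, ...
#' @export
generate_trait_table <- function(n_species, vocabulary = default_trait_vocabulary(),
                                 seed = 1L) {
  if (!is_count(n_species)) rfd_stop("configuration_error", "n_species must be a positive integer")
  if (length(vocabulary) == 0L || any(lengths(vocabulary) == 0L))
    rfd_stop("configuration_error", "empty vocabulary category")
  with_seed(seed, {
    cols <- lapply(vocabulary, function(mods) {
      x <- sample(mods, n_species, replace = TRUE)
      if (n_species >= length(mods)) {
        # guarantee coverage: one random slot per modality
        slots <- sample.int(n_species, length(mods))
        x[slots] <- sample(mods)
      }
      x
    })
    tab <- data.frame(taxon = sprintf("taxon_%02d", seq_len(n_species)),
                      cols, stringsAsFactors = FALSE)
    validate_trait_table(tab, vocabulary)
  })
}

# latent trophic targets: site main effect spanning the gradient plus a
# seasonal cycle peaking in spring (month 4) and lowest in winter, both
# collapsing to the midpoint for a degenerate (equal) range.
latent_targets <- function(config) {
  low <- config$gradient_range[1]; high <- config$gradient_range[2]
  centre <- (low + high) / 2; half <- (high - low) / 2
  site_score <- if (config$n_sites == 1L) 0 else
    seq(-1, 1, length.out = config$n_sites)
  month <- seq_len(config$n_months)
  season_score <- cos(2 * pi * (month - 4) / 12)   # +1 in April, -1 in October
  grid <- expand.grid(site = seq_len(config$n_sites), month = month)
  target <- centre + half * (0.7 * site_score[grid$site] +
                             0.3 * season_score[grid$month])
  data.frame(site = sprintf("site_%02d", grid$site), month = grid$month,
             sample_id = sprintf("S%02dM%02d", grid$site, grid$month),
             target = target, stringsAsFactors = FALSE)
}

#' Generate a water-chemistry table along the trophic gradient
#'
#' Draws latent composite-index targets across `gradient_range` (site main
#' effect plus a spring-peaking seasonal cycle), then back-solves each
#' parameter's concentration from its index equation with multiplicative
#' lognormal noise, so recomputing TLIc from the emitted chemistry recovers
#' the targets within about `10 * env_noise_sd` index units. Ancillary
#' physical variables (temp, dep, do, ph) are included for realism.
#'
#' @param config a [sim_config()].
#' @param coefficients coefficient set used for back-solving (default
#'   canonical).
#' @return data.frame: `sample_id`, `site`, `month`, `chla`, `tp`, `tn`,
#'   `sd`, `cod`, `temp`, `dep`, `do`, `ph`, plus the latent `target` as an
#'   attribute `latent_targets`.
#' @export
generate_env_gradient <- function(config = sim_config(),
                                  coefficients = tli_coefficients()) {
  lat <- latent_targets(config)
  seed <- child_seed(config$master_seed, "environment")
  with_seed(seed, {
    n <- nrow(lat)
    chem <- sapply(coefficients$params, function(p) {
      a <- coefficients$a[[p]]; b <- coefficients$b[[p]]
      exp((lat$target / 10 - a) / b + rnorm(n, 0, config$env_noise_sd))
    })
    env <- data.frame(lat[c("sample_id", "site", "month")], chem,
                      temp = pmax(0.5, 15 - 12 * cos(2 * pi * (lat$month - 7) / 12) +
                                    rnorm(n, 0, 1.5)),
                      dep = exp(rnorm(n, log(1.8), 0.2)),
                      do = pmax(2, rnorm(n, 8.5, 1.2)),
                      ph = rnorm(n, 8.1, 0.25),
                      stringsAsFactors = FALSE)
    # accidental sample loss, uniform over site-months
    n_drop <- round(config$missing_sample_rate * n)
    if (n_drop > 0) {
      drop <- sample.int(n, n_drop)
      env <- env[-drop, ]
      lat <- lat[-drop, ]
    }
    rownames(env) <- NULL
    attr(env, "latent_targets") <- lat
    env
  })
}

#' Generate communities by Gaussian environmental filtering
#'
#' Species respond to the per-sample latent trophic score T through Gaussian
#' niches: abundance of species i in sample s is proportional to
#' `baseline_i * exp(-kappa (T_s - opt_i)^2 / (2 w_i^2))` times lognormal
#' sampling noise, truncated at the detection limit. Species carrying the
#' configured tolerant modalities receive optima shifted toward the
#' eutrophic end and narrower niches, so strong filtering (large kappa)
#' concentrates abundance in a functionally clustered tolerant set at
#' high-trophic samples; at kappa = 0 abundances are independent of the
#' gradient.
#'
#' @param traits trait table (as from [generate_trait_table()]).
#' @param environment environment table from [generate_env_gradient()]
#'   (must carry the `latent_targets` attribute).
#' @param config a [sim_config()].
#' @return object of class `synthetic_dataset`: list with `community`,
#'   `traits`, `environment`, `truth` (per-species optimum, width, tolerance
#'   score; per-sample latent target) and `config`.
#' @export
generate_communities <- function(traits, environment, config = sim_config()) {
  if (nrow(traits) == 0L || nrow(environment) == 0L)
    rfd_stop("validation_error", "traits and environment must be nonempty")
  lat <- attr(environment, "latent_targets")
  if (is.null(lat) || !identical(lat$sample_id, environment$sample_id))
    rfd_stop("validation_error", "environment table lacks matching latent_targets")
  low <- config$gradient_range[1]; high <- config$gradient_range[2]
  range_w <- max(high - low, 1)
  seed <- child_seed(config$master_seed, "community")
  with_seed(seed, {
    n_sp <- nrow(traits)
    tol_score <- rowMeans(cbind(
      traits$feeding %in% config$tolerant_modalities,
      traits$trophi %in% config$tolerant_modalities,
      traits$swimming %in% config$tolerant_modalities))
    # the tolerant guild: carries at least two of the three tolerant
    # modalities, hence functionally clustered in trait space
    tolerant <- tol_score >= 2 / 3
    u <- runif(n_sp)
    # tolerant guild: broad plateau centred on the eutrophic quartile, so
    # its dominance is uniform across the most-eutrophic samples; sensitive
    # species: narrower niches spread over the meso range, so the low end
    # turns over gradually
    optimum <- ifelse(tolerant,
                      low + range_w * (0.85 + 0.1 * (u - 0.5)),
                      low + range_w * 0.6 * u)
    width <- range_w * ifelse(tolerant, runif(n_sp, 0.35, 0.55),
                              runif(n_sp, 0.18, 0.35))
    theta <- config$dominance_concentration
    baseline <- (2000 / n_sp) * exp(theta * rnorm(n_sp) - theta^2 / 2) *
      ifelse(tolerant, 6, 1)   # eutrophication winners are hyperabundant
    kappa <- config$filtering_strength
    niche <- exp(-kappa * outer(lat$target, optimum, "-")^2 /
                   matrix(2 * width^2, nrow(environment), n_sp, byrow = TRUE))
    noise <- matrix(exp(rnorm(nrow(environment) * n_sp, 0, 0.3)),
                    nrow(environment), n_sp)
    ab <- matrix(baseline, nrow(environment), n_sp, byrow = TRUE) * niche * noise
    ab[ab < config$detection_limit] <- 0
    # guarantee a live community everywhere: keep the single best-adapted
    # species above detection if filtering emptied a sample
    empty <- rowSums(ab) == 0
    if (any(empty)) {
      best <- max.col(niche[empty, , drop = FALSE] *
                        matrix(baseline, sum(empty), n_sp, byrow = TRUE))
      ab[cbind(which(empty), best)] <- config$detection_limit
    }
    colnames(ab) <- traits$taxon
    community <- data.frame(environment[c("sample_id", "site", "month")], ab,
                            stringsAsFactors = FALSE, check.names = FALSE)
    rownames(community) <- NULL
    truth <- list(
      species = data.frame(taxon = traits$taxon, optimum = optimum,
                           width = width, tolerance_score = tol_score,
                           baseline = baseline, stringsAsFactors = FALSE),
      samples = lat)
    structure(list(community = community, traits = traits,
                   environment = environment, truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' Run the full generator
#'
#' Trait table, environment gradient and filtered communities from one
#' configuration; stages use fixed child seeds of `master_seed` so the same
#' configuration is byte-identical on regeneration.
#'
#' @param config a [sim_config()].
#' @param coefficients coefficient set for the chemistry back-solve.
#' @return a `synthetic_dataset`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(master_seed = 7L))
#' dim(ds$community)
simulate_dataset <- function(config = sim_config(), coefficients = tli_coefficients()) {
  traits <- generate_trait_table(config$n_species, config$trait_vocabulary,
                                 seed = child_seed(config$master_seed, "traits"))
  env <- generate_env_gradient(config, coefficients)
  generate_communities(traits, env, config)
}

#' Write a synthetic dataset to canonical CSVs
#'
#' Emits the three canonical tables (abundance, traits, environment), the
#' truth table (per-species optimum/width) and a JSON echo of the
#' configuration. UTF-8, comma-delimited, header row, "." decimal.
#'
#' @param dataset a `synthetic_dataset`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("community.csv", "traits.csv", "environment.csv",
                               "truth_species.csv", "truth_samples.csv",
                               "config.json"))
  write.csv(dataset$community, paths[1], row.names = FALSE)
  write.csv(as.data.frame(dataset$traits), paths[2], row.names = FALSE)
  env <- dataset$environment; attr(env, "latent_targets") <- NULL
  write.csv(env, paths[3], row.names = FALSE)
  write.csv(dataset$truth$species, paths[4], row.names = FALSE)
  write.csv(dataset$truth$samples, paths[5], row.names = FALSE)
  cfg <- dataset$config
  cfg$trait_vocabulary <- lapply(cfg$trait_vocabulary, as.character)
  jsonlite::write_json(unclass(cfg), paths[6], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
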