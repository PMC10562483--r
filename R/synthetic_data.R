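# Seeded generators for survey sites, macrohabitat profiles and barrier
# inventories with the statistical structure the pipeline assumes, so every
# stage is testable without the restricted survey and inventory datasets.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators. Defaults emulate the study
#' setting: 15 macrohabitat types over 11 guilds with well separated
#' expected-community profiles; type-conditional physical attributes; the six
#' barrier types with impoundment-forming types rarer but taller; log-normal
#' heights (dams > weirs > sluices); a lowland/mountain slope mixture; and
#' per-type height-information proportions p and underreporting errors err
#' taken from the published inventory diagnostics for dams (p 0.483,
#' err 0.157), weirs (0.320, 0.582) and sluices (0.595, 0.720), with
#' illustrative values for the small types. Every fraction is overridable.
#'
#' @param seed integer RNG seed.
#' @param n_types number of macrohabitat types.
#' @param guilds guild ids.
#' @param concentration Dirichlet concentration of site-level guild
#'   proportions about their type profile (larger = tighter).
#' @param separation minimum pairwise city-block distance between type
#'   profiles.
#' @param barrier_freq named sampling weights over barrier types.
#' @param height_meanlog,height_sdlog named log-normal parameters (meters).
#' @param p_height named height-information proportions in (0, 1].
#' @param err named underreporting errors in [0, 1).
#' @param slope_meanlog,slope_sdlog log-normal slope components (per-mille)
#'   for the lowland and mountain mixture components.
#' @param mountain_fraction probability a barrier sits in a mountain segment.
#' @param n_catchments number of catchment ids.
#' @return List of class `sim_config`, JSON-serialisable.
#' @export
sim_config <- function(seed = 1L,
                       n_types = 15L,
                       guilds = champ_guilds()$id,
                       concentration = 60,
                       separation = 0.5,
                       barrier_freq = c(dam = 0.10, weir = 0.32,
                                        sluice = 0.03, culvert = 0.25,
                                        ford = 0.10, ramp = 0.20),
                       height_meanlog = c(dam = log(8), weir = log(1.5),
                                          sluice = log(1.2),
                                          culvert = log(0.6),
                                          ford = log(0.3), ramp = log(0.4)),
                       height_sdlog = c(dam = 0.9, weir = 0.6, sluice = 0.5,
                                        culvert = 0.4, ford = 0.3,
                                        ramp = 0.3),
                       p_height = c(dam = 0.483, weir = 0.320, sluice = 0.595,
                                    culvert = 0.25, ford = 0.25, ramp = 0.25),
                       err = c(dam = 0.157, weir = 0.582, sluice = 0.720,
                               culvert = 0.61, ford = 0.61, ramp = 0.61),
                       slope_meanlog = c(lowland = log(1.5),
                                         mountain = log(20)),
                       slope_sdlog = c(lowland = 0.6, mountain = 0.5),
                       mountain_fraction = 0.3,
                       n_catchments = 25L) {
  stopifnot(n_types >= 2, length(guilds) >= 2,
            all(p_height > 0 & p_height <= 1),
            all(err >= 0 & err < 1),
            all(barrier_freq >= 0), sum(barrier_freq) > 0,
            mountain_fraction >= 0, mountain_fraction <= 1)
  cfg <- list(seed = as.integer(seed), n_types = as.integer(n_types),
              guilds = guilds, concentration = concentration,
              separation = separation, barrier_freq = barrier_freq,
              height_meanlog = height_meanlog, height_sdlog = height_sdlog,
              p_height = p_height, err = err,
              slope_meanlog = slope_meanlog, slope_sdlog = slope_sdlog,
              mountain_fraction = mountain_fraction,
              n_catchments = as.integer(n_catchments))
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration
#'
#' @param config `sim_config`.
#' @param path JSON file path.
#' @return `read_sim_config` returns the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  named <- vapply(obj, function(x)
    is.numeric(x) && !is.null(names(x)), logical(1))
  obj[named] <- lapply(obj[named], as.list)   # keep names in JSON objects
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$guilds <- as.character(obj$guilds)
  vecs <- c("barrier_freq", "height_meanlog", "height_sdlog", "p_height",
            "err", "slope_meanlog", "slope_sdlog")
  obj[vecs] <- lapply(obj[vecs], unlist)
  do.call(sim_config, obj)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate separated macrohabitat profiles
#'
#' Draws one expected-guild-proportion profile per macrohabitat type from a
#' sparse Dirichlet and retries until all pairwise city-block distances reach
#' `config$separation`. Profiles are ordered so each type emphasises a
#' different part of the rheophilic-to-generalist guild gradient.
#'
#' @param config `sim_config`.
#' @param max_tries retry budget before giving up.
#' @return Named list of [champ_profile()]s (`t1` ... `tN`).
#' @export
generate_profiles <- function(config, max_tries = 200L) {
  g <- length(config$guilds)
  with_seed(config$seed, {
    for (try in seq_len(max_tries)) {
      # anchor each type on a rotating dominant guild to aid separation
      alpha <- matrix(0.4, config$n_types, g)
      dom <- ((seq_len(config$n_types) - 1L) %% g) + 1L
      alpha[cbind(seq_len(config$n_types), dom)] <- 6
      pr <- t(vapply(seq_len(config$n_types), function(i)
        rdirichlet(1, alpha[i, ])[1, ], numeric(g)))
      dmin <- min(stats::dist(pr, method = "manhattan"))
      if (dmin >= config$separation) {
        colnames(pr) <- config$guilds
        out <- lapply(seq_len(config$n_types), function(i)
          champ_profile(pr[i, ], type_id = paste0("t", i)))
        names(out) <- paste0("t", seq_len(config$n_types))
        return(out)
      }
    }
    stop("could not attain profile separation ", config$separation,
         " in ", max_tries, " tries", call. = FALSE)
  })
}

# Type-conditional physical attribute parameters, deterministic in the type
# index: types cycle through geology / climate and trend in catchment size.
type_attribute_params <- function(config) {
  i <- seq_len(config$n_types)
  data.frame(
    type = paste0("t", i),
    slope_meanlog = log(1 + 29 * (i - 1) / max(1, config$n_types - 1)),
    altitude_mean = 50 + 1400 * (i - 1) / max(1, config$n_types - 1),
    strahler_mean = 2 + (i %% 5),
    catchment_meanlog = log(50) + 2.5 * ((i - 1) %% 3),
    geology = c("calcareous", "siliceous", "organic")[(i %% 3) + 1],
    climate_zone = c("atlantic", "continental", "mediterranean", "boreal",
                     "alpine")[(i %% 5) + 1],
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic survey sites
#'
#' Guild proportions are Dirichlet draws centred on the site's type profile
#' with concentration `config$concentration`; physical attributes come from
#' type-conditional distributions (log-normal slope and catchment area,
#' normal altitude, Poisson-shifted Strahler order, fixed geology and climate
#' per type). True type labels are kept for recovery tests.
#'
#' @param config `sim_config`.
#' @param profiles output of [generate_profiles()].
#' @param sites_per_type number of sites for each macrohabitat type.
#' @return data.frame in the survey schema (`site_id`, physical attributes,
#'   one column per guild) plus a `type` column of true labels.
#' @export
generate_sites <- function(config, profiles,
                           sites_per_type = 20L) {
  if (sites_per_type == 0L) {
    return(data.frame())
  }
  pars <- type_attribute_params(config)
  with_seed(config$seed + 1L, {
    rows <- lapply(seq_along(profiles), function(i) {
      pf <- as.numeric(profiles[[i]])
      gp <- rdirichlet(sites_per_type, pf * config$concentration + 1e-6)
      colnames(gp) <- config$guilds
      data.frame(
        site_id = sprintf("s%02d_%03d", i, seq_len(sites_per_type)),
        slope_permil = stats::rlnorm(sites_per_type,
                                     pars$slope_meanlog[i], 0.4),
        altitude_m = pmax(0, stats::rnorm(sites_per_type,
                                          pars$altitude_mean[i], 60)),
        strahler = pmax(1L, stats::rpois(sites_per_type,
                                         pars$strahler_mean[i])),
        catchment_km2 = stats::rlnorm(sites_per_type,
                                      pars$catchment_meanlog[i], 0.5),
        geology = pars$geology[i],
        climate_zone = pars$climate_zone[i],
        gp,
        type = names(profiles)[i],
        stringsAsFactors = FALSE, check.names = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic barrier inventory
#'
#' Draws a full barrier population (types by `barrier_freq`; log-normal
#' heights per type; slopes from the lowland/mountain mixture; catchments and
#' macrohabitat types uniform), then emulates the observation process:
#' a fraction `err[b]` of each type is dropped entirely (underreporting) and
#' the heights of a fraction `1 - p_height[b]` of the remainder are blanked.
#' Missingness is independent of barrier size unless `size_biased` is set, in
#' which case the smallest barriers are preferentially underreported (to
#' exercise the estimator's bias under violated assumptions).
#'
#' @param config `sim_config`.
#' @param n_barriers size of the full population.
#' @param macrohabitats macrohabitat ids to assign to barriers.
#' @param size_biased logical; bias underreporting toward small barriers.
#' @return List: `full` (complete population with `true_L_km`), `reported`
#'   (observed inventory with missing heights as NA), `true_totals`
#'   (data.frame of true impoundment km and counts by type).
#' @export
generate_barriers <- function(config, n_barriers = 2000L,
                              macrohabitats = paste0("t", 1:15),
                              size_biased = FALSE) {
  with_seed(config$seed + 2L, {
    ty <- sample(names(config$barrier_freq), n_barriers, replace = TRUE,
                 prob = config$barrier_freq)
    h <- stats::rlnorm(n_barriers, config$height_meanlog[ty],
                       config$height_sdlog[ty])
    mountain <- stats::runif(n_barriers) < config$mountain_fraction
    comp <- ifelse(mountain, "mountain", "lowland")
    s <- stats::rlnorm(n_barriers, config$slope_meanlog[comp],
                       config$slope_sdlog[comp])
    full <- data.frame(
      barrier_id = sprintf("b%05d", seq_len(n_barriers)),
      type = ty,
      height_m = h,
      slope_permil = s,
      catchment_id = sprintf("c%02d", sample.int(config$n_catchments,
                                                 n_barriers, replace = TRUE)),
      fcmacht_id = sample(macrohabitats, n_barriers, replace = TRUE),
      upstream_km = stats::rlnorm(n_barriers, log(5), 1),
      stringsAsFactors = FALSE)
    full$true_L_km <- full$height_m / full$slope_permil

    # observation process: drop err[b] of each type, blank 1-p of heights
    keep_prob <- 1 - config$err[ty]
    if (size_biased) {
      # small barriers twice as likely to be missed, same type-level mean
      rk <- stats::ave(full$height_m, ty, FUN = function(x)
        rank(x) / length(x))
      keep_prob <- pmin(1, pmax(0, keep_prob * (0.5 + rk)))
    }
    reported <- full[stats::runif(n_barriers) < keep_prob, , drop = FALSE]
    blank <- stats::runif(nrow(reported)) >= config$p_height[reported$type]
    reported$height_m[blank] <- NA_real_
    reported$true_L_km <- NULL

    agg <- stats::aggregate(true_L_km ~ type, data = full, sum)
    cnt <- as.data.frame(table(type = full$type), stringsAsFactors = FALSE)
    tot <- merge(agg, cnt, by = "type")
    names(tot) <- c("type", "true_impoundment_km", "true_count")
    list(full = full, reported = reported, true_totals = tot)
  })
}
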