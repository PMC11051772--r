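# Seeded synthetic-data generators with known ground truth: copy-number
# calibration sets, latitude-banded communities with environmental tables,
# and grazer-prey batch-culture dynamics. Every generator takes a seed and
# reproduces its output bit-identically.

#' Simulate a copy-number calibration data set
#'
#' Biovolumes uniform on `biovolume_range`; copies per cell follow
#' `intercept + slope * biovolume` plus Gaussian noise.
#'
#' @param slope,intercept true line (copies per um^3 and copies).
#' @param n number of calibration points.
#' @param noise_sd Gaussian noise standard deviation (copies); 0 for exact
#'   recovery tests.
#' @param biovolume_range range of biovolumes in um^3; the default 65-523
#'   covers small cells of 5-10 um equivalent diameter.
#' @param group group label attached to all points.
#' @param seed integer seed.
#' @return calibration data.frame (`group`, `biovolume_um3`,
#'   `copies_per_cell`).
#' @export
simulate_copy_dataset <- function(slope, intercept, n = 50, noise_sd = 0,
                                  biovolume_range = c(65, 523),
                                  group = "other", seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n < 2L) stop("need n >= 2")
  if (any(biovolume_range <= 0)) stop("biovolume range must be positive")
  set.seed(seed)
  v <- runif(n, biovolume_range[1L], biovolume_range[2L])
  y <- intercept + slope * v + rnorm(n, 0, noise_sd)
  data.frame(group = group, biovolume_um3 = v, copies_per_cell = y)
}

#' Default community simulation configuration
#'
#' Encodes the study conditions the generator emulates: four latitudinal
#' bands (0-20, 20-30, 30-40, 40-60 degrees) with surface medians of
#' photosynthetically available radiation (25.4 / 24.3 / 14.7 / 18.8 mol
#' photons m^-2 d^-1), nitrate+nitrite (0.89 / 0.03 / 0.13 / 17.3 umol
#' L^-1), heterotrophic bacteria (4.9 / 3.9 / 5.3 / 4.5 x 1e5 cells mL^-1),
#' temperature and salinity; station counts proportional to 36/17/37/14; a
#' logistic model of the mixotroph index on standardised log light
#' (positive effect) and log nutrients (negative effect); and group-wise
#' rRNA copy-number inflation.
#'
#' @param n_stations number of stations (default 104).
#' @param cml_stations how many stations also get a chlorophyll-maximum
#'   sample (default 61 when `n_stations` is 104, proportionally
#'   otherwise).
#' @param beta_par,beta_n effects of standardised log10 light and log10
#'   nutrients on logit mixotroph index (defaults +0.5 and -1.0).
#' @param ti_noise_sd logit-scale station noise on the mixotroph index.
#' @param cml_shift additive logit shift of the mixotroph index in
#'   chlorophyll-maximum samples beyond what their light/nutrient values
#'   already imply (default -0.2, i.e. lower at depth).
#' @param n_lineages named counts of lineages per mode
#'   (M/A/H/unknown).
#' @param cf_map correction factors used to inflate cell abundances into
#'   gene abundances.
#' @param total_cells community cell total per sample.
#' @param depth sequencing depth for multinomial resampling.
#' @param resample multinomially resample gene counts to `depth` (TRUE) or
#'   return exact gene values (FALSE; noise-free).
#' @param cf_noise_cv multiplicative log-normal noise CV on the per-lineage
#'   copy-number inflation (0 = exact).
#' @param frac_unknown fraction of the community carried by
#'   unknown-mode lineages.
#' @param missing_rate fraction of environmental cells blanked to missing.
#' @return config list for [simulate_community()].
#' @export
community_sim_config <- function(n_stations = 104,
                                 cml_stations = round(n_stations * 61 / 104),
                                 beta_par = 0.5, beta_n = -1.0,
                                 ti_noise_sd = 0.2, cml_shift = -0.2,
                                 n_lineages = c(M = 25, A = 30, H = 40,
                                                unknown = 5),
                                 cf_map = cf_preset(),
                                 total_cells = 1e4,
                                 depth = 1e5, resample = TRUE,
                                 cf_noise_cv = 0,
                                 frac_unknown = 0.03,
                                 missing_rate = 0.02) {
  bands <- data.frame(
    band = c("0-20", "20-30", "30-40", "40-60"),
    weight = c(36, 17, 37, 14),
    par = c(25.4, 24.3, 14.7, 18.8),
    no3_no2 = c(0.89, 0.03, 0.13, 17.3),
    hbac = c(4.9e5, 3.9e5, 5.3e5, 4.5e5),
    temperature = c(26.6, 24.7, 19.5, 7.1),
    salinity = c(35.1, 36.2, 36.4, 34.3),
    sdlog10_par = 0.08, sdlog10_n = 0.35, sdlog10_hbac = 0.1)
  list(n_stations = n_stations, cml_stations = cml_stations, bands = bands,
       beta_par = beta_par, beta_n = beta_n, ti_noise_sd = ti_noise_sd,
       cml_shift = cml_shift, n_lineages = n_lineages, cf_map = cf_map,
       total_cells = total_cells, depth = depth, resample = resample,
       cf_noise_cv = cf_noise_cv, frac_unknown = frac_unknown,
       missing_rate = missing_rate,
       ti_a_share = 0.21 / (0.21 + 0.47))   # autotroph share of the A+H remainder
}

# build the synthetic lineage universe: taxonomy, modes, annotation table
build_lineage_universe <- function(n_lineages) {
  mk <- function(mode, n, prefix) {
    if (n == 0L) return(NULL)
    id <- sprintf("%s%02d", prefix, seq_len(n))
    data.frame(lineage_id = id, mode = mode, stringsAsFactors = FALSE)
  }
  lin <- rbind(mk("M", n_lineages[["M"]], "mixo"),
               mk("A", n_lineages[["A"]], "auto"),
               mk("H", n_lineages[["H"]], "het"),
               mk("unknown", n_lineages[["unknown"]], "unk"))
  n <- nrow(lin)
  # spread copy-number groups across modes: some dinoflagellate mixotrophs
  # and heterotrophs, some diatom autotrophs, the rest 'other'
  division <- rep("Haptophyta", n)
  class_ <- rep("Prymnesiophyceae", n)
  i <- seq_len(n)
  dino <- (lin$mode == "M" & (i %% 5 == 0)) | (lin$mode == "H" & (i %% 7 == 0))
  diat <- lin$mode == "A" & (i %% 4 == 0)
  division[dino] <- "Dinoflagellata"; class_[dino] <- "Dinophyceae"
  division[diat] <- "Ochrophyta";     class_[diat] <- "Bacillariophyta"
  genus <- paste0("Genus_", lin$lineage_id)
  species <- paste0(genus, "_sp.")
  path <- paste("Eukaryota", "SAR", division, class_,
                paste0("Order_", lin$lineage_id),
                paste0("Family_", lin$lineage_id), genus, species, sep = ";")
  tx <- taxonomy_table(lin$lineage_id, path)
  annotated <- lin$mode != "unknown"
  db <- trophic_db(data.frame(taxon = species[annotated], rank = "species",
                              mode = lin$mode[annotated],
                              source = "synthetic", stringsAsFactors = FALSE))
  list(lineages = lin, taxonomy = tx, db = db)
}

#' Simulate a banded plankton community with known trophic structure
#'
#' Draws station environments log-normally around latitudinal-band medians,
#' sets each sample's true mixotroph index through a logistic link on
#' standardised log10 light and log10 nutrients, fills the autotroph /
#' heterotroph remainder at a fixed share, spreads mode totals over
#' lineages with log-normal weights, inflates cell abundances into gene
#' abundances with group-specific copy-number factors, and (optionally)
#' multinomially resamples reads to sequencing depth. The returned ground
#' truth makes every pipeline stage testable.
#'
#' @param config a [community_sim_config()].
#' @param seed integer seed; identical seeds reproduce output
#'   bit-identically.
#' @return list with `abundance` (gene-mode `abundance_table`), `taxonomy`,
#'   `db` (trophic annotations), `env` (`env_table` with the 29 registry
#'   variables), `truth` (per-sample true indices, band, layer; per-lineage
#'   modes), and the `config`.
#' @export
simulate_community <- function(config = community_sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  bands <- cfg$bands
  # station band membership proportional to band weights
  n_band <- floor(bands$weight / sum(bands$weight) * cfg$n_stations)
  while (sum(n_band) < cfg$n_stations)
    n_band[which.max(bands$weight / sum(bands$weight) * cfg$n_stations - n_band)] <-
      n_band[which.max(bands$weight / sum(bands$weight) * cfg$n_stations - n_band)] + 1L
  band_of <- rep(seq_len(nrow(bands)), n_band)
  station_id <- sprintf("ST%03d", seq_len(cfg$n_stations))

  draw_ln <- function(median_, sdlog10) 10^(log10(median_) + rnorm(length(median_), 0, sdlog10))
  sur <- data.frame(
    sample_id = paste0(station_id, "_SUR"), station_id = station_id,
    layer = "SUR", band = bands$band[band_of],
    par_8d = draw_ln(bands$par[band_of], bands$sdlog10_par[band_of]),
    no3_no2 = draw_ln(bands$no3_no2[band_of], bands$sdlog10_n[band_of]),
    het_bacteria = draw_ln(bands$hbac[band_of], bands$sdlog10_hbac[band_of]),
    temperature = bands$temperature[band_of] + rnorm(cfg$n_stations, 0, 1.5),
    salinity = bands$salinity[band_of] + rnorm(cfg$n_stations, 0, 0.3),
    stringsAsFactors = FALSE)
  samples <- sur
  if (cfg$cml_stations > 0) {
    pick <- sort(sample.int(cfg$n_stations, cfg$cml_stations))
    cml <- sur[pick, , drop = FALSE]
    cml$sample_id <- paste0(station_id[pick], "_CML")
    cml$layer <- "CML"
    cml$par_8d <- cml$par_8d * 10^rnorm(cfg$cml_stations, log10(0.85), 0.05)
    cml$no3_no2 <- cml$no3_no2 * 10^rnorm(cfg$cml_stations, log10(1.2), 0.08)
    cml$het_bacteria <- cml$het_bacteria * 10^rnorm(cfg$cml_stations, log10(0.9), 0.05)
    samples <- rbind(sur, cml)
  }
  ns <- nrow(samples)

  # true mixotroph index via a logistic link on log gradients standardised
  # against the surface samples (so the link does not depend on how many
  # depth samples are drawn)
  zscore_sur <- function(x) {
    ref <- log10(x[samples$layer == "SUR"])
    (log10(x) - mean(ref)) / sd(ref)
  }
  zpar <- zscore_sur(samples$par_8d)
  zn <- zscore_sur(samples$no3_no2)
  a0 <- stats::qlogis(0.29 / (1 - cfg$frac_unknown))
  eta <- a0 + cfg$beta_par * zpar + cfg$beta_n * zn +
    rnorm(ns, 0, cfg$ti_noise_sd) +
    ifelse(samples$layer == "CML", cfg$cml_shift, 0)
  ti_m <- stats::plogis(eta) * (1 - cfg$frac_unknown)
  remainder <- 1 - cfg$frac_unknown - ti_m
  if (any(remainder <= 0))
    stop("effect sizes push the mixotroph index past 1 in band(s): ",
         paste(unique(samples$band[remainder <= 0]), collapse = ", "))
  ti_a <- remainder * cfg$ti_a_share
  ti_h <- remainder - ti_a
  ti_unknown <- rep(cfg$frac_unknown, ns)

  uni <- build_lineage_universe(cfg$n_lineages)
  modes <- uni$lineages$mode
  nlin <- nrow(uni$lineages)

  # per-sample per-lineage cell abundances: log-normal weights within mode,
  # scaled to the mode's share of the community total
  cells <- matrix(0, ns, nlin,
                  dimnames = list(samples$sample_id, uni$lineages$lineage_id))
  share <- cbind(M = ti_m, A = ti_a, H = ti_h, unknown = ti_unknown)
  for (g in colnames(share)) {
    cols <- which(modes == g)
    if (!length(cols)) next
    w <- matrix(rlnorm(ns * length(cols), 0, 1), ns, length(cols))
    w <- w / rowSums(w)
    cells[, cols] <- w * share[, g] * cfg$total_cells
  }

  grp <- setNames(uni$taxonomy$cf_group, uni$taxonomy$lineage_id)
  cfv <- cfg$cf_map[grp[colnames(cells)]]
  genes <- sweep(cells, 2L, cfv, `*`)
  if (cfg$cf_noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$cf_noise_cv^2))
    genes <- genes * matrix(rlnorm(length(genes), -sdlog^2 / 2, sdlog),
                            nrow(genes))
  }
  if (cfg$resample) {
    counts <- t(apply(genes, 1L, function(row)
      rmultinom(1L, size = cfg$depth, prob = row)[, 1L]))
    dimnames(counts) <- dimnames(genes)
    ab <- abundance_table(counts, "gene")
  } else {
    ab <- abundance_table(genes, "gene", check_integer = FALSE)
  }

  env_df <- cbind(samples[c("sample_id", "station_id", "layer")],
                  synth_env_block(samples, cfg))
  env <- env_table(env_df)

  truth <- list(
    samples = data.frame(sample_id = samples$sample_id,
                         station_id = samples$station_id,
                         layer = samples$layer, band = samples$band,
                         TI_M = ti_m, TI_A = ti_a, TI_H = ti_h,
                         TI_unknown = ti_unknown, stringsAsFactors = FALSE),
    lineage_modes = setNames(modes, uni$lineages$lineage_id),
    cells = cells,
    beta_par = cfg$beta_par, beta_n = cfg$beta_n)
  list(abundance = ab, taxonomy = uni$taxonomy, db = uni$db, env = env,
       truth = truth, config = cfg)
}

# the remaining registry variables: plausible scales, partly band-driven,
# with a configurable fraction blanked to missing
synth_env_block <- function(samples, cfg) {
  ns <- nrow(samples)
  ln <- function(med, sdlog10 = 0.15) 10^(log10(med) + rnorm(ns, 0, sdlog10))
  out <- data.frame(
    temperature = samples$temperature,
    salinity = samples$salinity,
    density = 1025 + (30 - samples$temperature) * 0.2 + rnorm(ns, 0, 0.2),
    kd_par = ln(0.05, 0.2),
    cml_depth = ln(60, 0.25),
    mld = ln(40, 0.3),
    nitracline_depth = ln(80, 0.3),
    euphotic_depth = ln(90, 0.2),
    par_8d = samples$par_8d,
    par_30d = samples$par_8d * 10^rnorm(ns, 0, 0.05),
    sunshine_duration = pmin(pmax(rnorm(ns, 8, 2), 1), 14),
    chl_a = ln(0.2, 0.3),
    oxygen = ln(210, 0.05),
    no3_no2 = samples$no3_no2,
    no2 = samples$no3_no2 * 10^rnorm(ns, log10(0.1), 0.2),
    po4 = samples$no3_no2 * 10^rnorm(ns, log10(0.08), 0.25) + 0.01,
    sio4 = ln(2, 0.4),
    ph = rnorm(ns, 8.05, 0.03),
    total_alkalinity = ln(2300, 0.02),
    total_carbon = ln(2050, 0.02),
    fluorescence = ln(0.3, 0.3),
    poc = ln(3, 0.3),
    pic = ln(0.2, 0.35),
    cdom = ln(1.5, 0.3),
    pco2 = ln(400, 0.05),
    npp = ln(300, 0.3),
    prochlorococcus = ln(8e4, 0.4),
    synechococcus = ln(1.5e4, 0.5),
    het_bacteria = samples$het_bacteria)
  if (cfg$missing_rate > 0) {
    m <- matrix(runif(ns * ncol(out)) < cfg$missing_rate, ns)
    # keep the headline gradients complete so regressions stay paired
    m[, match(c("par_8d", "no3_no2", "het_bacteria"), names(out))] <- FALSE
    out[m] <- NA
  }
  out
}

#' Default culture simulation configuration
#'
#' Emulates the batch-culture setup used for mixotroph isolates: prey
#' (a *Prochlorococcus*-like bacterium) at ~2e6 cells mL^-1, a grazer
#' inoculum growing exponentially, constant true clearance, sampling every
#' 12-24 h and log-normal measurement noise.
#'
#' @param clearance true clearance rate C* (mL grazer^-1 h^-1).
#' @param mu grazer intrinsic growth rate (h^-1).
#' @param prey0 initial prey concentration (cells mL^-1).
#' @param grazer0 initial grazer concentration (cells mL^-1); the default
#'   2e3 grows to ~9e4 over a 96 h experiment at the default growth rate,
#'   matching the 1e4-1e5 cells mL^-1 final densities typical of these
#'   prey-supplemented cultures.
#' @param prey_rate prey intrinsic net rate (h^-1); applies to the grazed
#'   culture and the grazer-free control alike (0 by default, so the
#'   control is flat and the true clearance is identifiable without
#'   control correction).
#' @param interval_h sampling interval in hours (12-24).
#' @param horizon_h experiment duration in hours.
#' @param noise_cv log-normal measurement noise coefficient of variation
#'   (0 = exact).
#' @param replicates number of replicate cultures.
#' @param grazer_biovolume grazer biovolume (um^3).
#' @param prey_sat prey concentration above which clearance saturates
#'   (ingestion capped at `clearance * prey_sat`); `Inf` disables the
#'   functional response and keeps clearance constant.
#' @return config list for [simulate_culture()].
#' @export
culture_sim_config <- function(clearance = 2e-6, mu = 0.04,
                               prey0 = 2e6, grazer0 = 2e3,
                               prey_rate = 0, interval_h = 12,
                               horizon_h = 96, noise_cv = 0,
                               replicates = 1, grazer_biovolume = 100,
                               prey_sat = Inf) {
  if (interval_h < 12 || interval_h > 24)
    warning("sampling interval outside the conventional 12-24 h range")
  if (horizon_h < 2 * interval_h)
    stop("horizon shorter than two sampling intervals")
  list(clearance = clearance, mu = mu, prey0 = prey0, grazer0 = grazer0,
       prey_rate = prey_rate, interval_h = interval_h,
       horizon_h = horizon_h, noise_cv = noise_cv,
       replicates = replicates, grazer_biovolume = grazer_biovolume,
       prey_sat = prey_sat)
}

#' Simulate grazer-prey batch-culture dynamics
#'
#' Integrates `dP/dt = r_P P - c(P) P G`, `dG/dt = mu G` on a 0.1 h grid
#' (`c(P)` the constant clearance, optionally saturating above `prey_sat`),
#' samples at the configured interval, and applies log-normal measurement
#' noise. The grazer-free control integrates `dP/dt = r_P P`. The truth
#' record stores the parameters, the fine-grid trajectories and the
#' cumulative prey removed by grazing.
#'
#' @param config a [culture_sim_config()].
#' @param seed integer seed.
#' @return list with `series` (list of `culture_ts`, one per replicate) and
#'   `truth` (`clearance`, `mu`, `prey_rate`, `fine` data.frame of the
#'   noise-free 0.1 h trajectories, `removed_total`).
#' @export
simulate_culture <- function(config = culture_sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  grid <- seq(0, cfg$horizon_h, by = 0.1)
  rhs <- function(t, y, p) {
    G <- cfg$grazer0 * exp(cfg$mu * t)
    cl <- if (is.finite(cfg$prey_sat) && y[1L] > cfg$prey_sat)
      cfg$clearance * cfg$prey_sat / y[1L] else cfg$clearance
    list(c(cfg$prey_rate * y[1L] - cl * y[1L] * G,   # grazed prey
           cfg$prey_rate * y[2L],                    # control prey
           cl * y[1L] * G))                          # cumulative removed
  }
  sol <- deSolve::ode(c(P = cfg$prey0, Pc = cfg$prey0, R = 0),
                      grid, rhs, parms = NULL, method = "ode45")
  fine <- data.frame(time = sol[, "time"], prey = sol[, "P"],
                     control_prey = sol[, "Pc"],
                     grazer = cfg$grazer0 * exp(cfg$mu * sol[, "time"]),
                     removed = sol[, "R"])
  t_obs <- seq(0, cfg$horizon_h, by = cfg$interval_h)
  at <- match(round(t_obs, 6), round(fine$time, 6))
  noisy <- function(x) {
    if (cfg$noise_cv == 0) return(x)
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    x * rlnorm(length(x), -sdlog^2 / 2, sdlog)
  }
  series <- lapply(seq_len(cfg$replicates), function(r)
    culture_time_series(t_obs,
                        grazer = noisy(fine$grazer[at]),
                        prey = noisy(fine$prey[at]),
                        control_prey = noisy(fine$control_prey[at]),
                        grazer_biovolume = cfg$grazer_biovolume,
                        replicate_id = paste0("r", r)))
  list(series = series,
       truth = list(clearance = cfg$clearance, mu = cfg$mu,
                    prey_rate = cfg$prey_rate, fine = fine,
                    removed_total = tail(fine$removed, 1L)))
}

#' Write a simulated community to the package's on-disk formats
#'
#' Emits the abundance TSV, taxonomy TSV, annotation TSV and environment
#' CSV for a [simulate_community()] result.
#'
#' @param sim a [simulate_community()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             trophic_db = file.path(dir, "trophic_db.tsv"),
             env = file.path(dir, "env.csv"))
  ab <- sim$abundance
  if (abundance_mode(ab) == "gene")
    ab <- as_abundance(round(unclass(ab), 6), "gene")
  write_abundance(ab, paths["abundance"])
  tx <- sim$taxonomy
  ranked <- apply(as.matrix(tx[, PR2_RANKS]), 1L, paste, collapse = ";")
  write.table(data.frame(lineage_id = tx$lineage_id, ranked_path = ranked),
              paths["taxonomy"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(sim$db), paths["trophic_db"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_env_table(sim$env, paths["env"])
  paths
}
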