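# Shared builders for tests: species tables on the default class-key
# grid, constant / synthetic driver series, and the seeded calibration
# recovery experiment.

# A fixed six-species table on the class grid whose suitabilities under
# the default synthetic drivers are deliberately uneven, so the
# community has clear dominants (covers roughly 0.07-0.28).
recovery_true_table <- function(key = default_class_key()) {
  df <- data.frame(
    name = c("sp_dom1", "sp_dom2", "sp_dom3", "sp_mid", "sp_sub1", "sp_sub2"),
    ph_class       = c(2, 2, 3, 3, 2, 2),
    n_class        = c(1, 2, 1, 2, 1, 2),
    moisture_class = c(3, 3, 3, 3, 2, 2),
    light_class    = c(1, 1, 1, 2, 1, 1),
    tmin = 0, tmax = 30,
    rooting_class  = c(2, 3, 2, 2, 1, 1),
    shading_class  = c(3, 4, 2, 2, 1, 1),
    stringsAsFactors = FALSE
  )
  species_table(df, key = key, provenance = "recovery truth")
}

# Random species table on the class-key grid. light_min_class = 2 keeps
# every light optimum above any forest-floor light level, i.e. the
# light-limited regime in which more light always helps.
random_species_table <- function(seed, n = 5, light_min_class = 1,
                                 key = default_class_key()) {
  withr::with_seed(seed, {
    df <- data.frame(
      name = sprintf("sp%02d", seq_len(n)),
      ph_class = sample(2:4, n, replace = TRUE),
      n_class = sample(1:2, n, replace = TRUE),
      moisture_class = sample(2:4, n, replace = TRUE),
      light_class = sample(light_min_class:3, n, replace = TRUE),
      tmin = 0, tmax = 30,
      rooting_class = sample(1:3, n, replace = TRUE),
      shading_class = sample(1:5, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    species_table(df, key = key, provenance = sprintf("random seed %d", seed))
  })
}

# Noise-free, season-free, trend-free drivers: every month identical.
constant_drivers <- function(years = 2001:2002, pH = 4.3, N = 1.2,
                             moisture = 0.6, temperature = 10, light = 0.15) {
  cfg <- synthetic_driver_config(
    years = years,
    pH = list(baseline = pH, amplitude = 0, trend_decade = 0, noise = 0,
              depth_gradient = 0),
    N = list(baseline = N, amplitude = 0, trend_decade = 0, noise = 0,
             depth_gradient = 0),
    moisture = list(baseline = moisture, amplitude = 0, trend_decade = 0,
                    noise = 0, depth_gradient = 0),
    temperature = list(baseline = temperature, amplitude = 0, trend_decade = 0,
                       noise = 0, depth_gradient = 0),
    light = list(baseline = light, amplitude = 0, trend_decade = 0, noise = 0,
                 depth_gradient = 0),
    seed = 1L)
  generate_synthetic_drivers(cfg)
}

# One seeded niche-recovery experiment: simulate a known table to get
# "observed" covers, displace the niche optima of the 1-3 most dominant
# species by two classes away from the prevailing driver value (the
# blind table), then calibrate the blind table back. Returns blind and
# calibrated CzI and the recovery flag.
recovery_experiment <- function(seed, years = 2001:2003) {
  key <- default_class_key()
  truth <- recovery_true_table(key)
  series <- generate_synthetic_drivers(synthetic_driver_config(
    years = years, seed = seed))
  observed <- covers_at(suppressWarnings(simulate_community(truth, series)))

  axis_cols <- c(light = "light_class", N = "n_class", pH = "ph_class")
  withr::with_seed(seed + 1000L, {
    k <- sample(1:3, 1)
    targets <- order(observed, decreasing = TRUE)[seq_len(k)]
    blind <- truth
    for (i in targets) {
      axis <- sample(names(axis_cols), 1)
      col <- axis_cols[[axis]]
      r <- blind[[col]][i]
      # displace away from the driver: prefer moving up unless at the top
      r2 <- if (r + 2 <= 5) r + 2L else r - 2L
      blind <- vegniche:::set_axis_rank(blind, i, axis, r2, key)
    }
  })
  blind_covers <- covers_at(suppressWarnings(simulate_community(blind, series)))
  czi_blind <- czekanowski(blind_covers, observed)
  res <- calibrate(blind, series, observed, key = key)
  list(
    czi_blind = czi_blind,
    czi_cal = czekanowski(res$report$final_covers, observed),
    recovered = res$report$converged,
    report = res$report,
    displaced = truth$name[targets]
  )
}

# Brute-force re-implementations of the metric suite, written as plain
# elementwise loops, kept independent of the package internals.
oracle_nae <- function(p, o) {
  sp <- 0; so <- 0
  for (i in seq_along(p)) { sp <- sp + p[i]; so <- so + o[i] }
  pb <- sp / length(p); ob <- so / length(o)
  (pb - ob) / ob
}
oracle_nrmse <- function(p, o) {
  ss <- 0
  for (i in seq_along(p)) ss <- ss + (p[i] - o[i])^2
  so <- 0
  for (i in seq_along(o)) so <- so + o[i]
  sqrt(ss / length(p)) / (so / length(o))
}
oracle_one_to_one <- function(p, o) {
  spo <- 0; so2 <- 0
  for (i in seq_along(p)) { spo <- spo + p[i] * o[i]; so2 <- so2 + o[i]^2 }
  slope <- spo / so2
  sr <- 0
  for (i in seq_along(p)) sr <- sr + (p[i] - slope * o[i])^2
  se <- sqrt(sr / (length(p) - 1) / so2)
  pb <- mean(p); ob <- mean(o)
  num <- 0; dp <- 0; do_ <- 0
  for (i in seq_along(p)) {
    num <- num + (p[i] - pb) * (o[i] - ob)
    dp <- dp + (p[i] - pb)^2
    do_ <- do_ + (o[i] - ob)^2
  }
  list(slope = slope, se = se, correlation = num / sqrt(dp * do_))
}
oracle_czi <- function(p, o) {
  sad <- 0; ssum <- 0
  for (i in seq_along(p)) {
    sad <- sad + abs(p[i] - o[i])
    ssum <- ssum + p[i] + o[i]
  }
  1 - sad / ssum
}
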