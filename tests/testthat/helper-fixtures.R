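# Shared fixtures, built in code. The heavier synthetic cohort used by several
# tests is generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# a small 3-channel table for fast unit tests
tiny_channels <- function() {
  validate_channel_table(rbind(
    channel_spec(365, 420, 465, index = 0),
    channel_spec(390, 466, 511, index = 1),
    channel_spec(440, 512, 557, index = 2)
  ))
}

# small two-group config: modest NADH-like shift, small field
small_config <- function(seed = 1, groups = c("G1", "G2"),
                         patients_per_group = 3, cells_per_patient = c(4, 4),
                         ...) {
  fl <- default_fluorophores()
  base <- rbind(c(1.0, 0.6), c(1.6, 0.6), c(1.0, 1.0))
  am <- base[seq_along(groups), , drop = FALSE]
  rownames(am) <- groups
  colnames(am) <- names(fl)
  cohort_config(groups = groups, patients_per_group = patients_per_group,
                cells_per_patient = cells_per_patient, fluorophores = fl,
                abundance_means = am, field_px = 96,
                cell_radius_px = c(8, 12), seed = seed, ...)
}

# planted-marker panel: broad baseline + narrow marker doubled in group G2;
# exactly three channels are informative at the 10% margin
marker_config <- function(seed = 1, patients_per_group = 4,
                          cells_per_patient = c(5, 5)) {
  panel <- list(
    baseline = fluorophore("baseline", 400, 60, 520, 60, brightness = 1),
    marker = fluorophore("marker", 465, 9, 535, 22, brightness = 1))
  am <- rbind(c(1, 0.5), c(1, 1.0))
  rownames(am) <- c("G1", "G2"); colnames(am) <- names(panel)
  cohort_config(groups = c("G1", "G2"), patients_per_group = patients_per_group,
                cells_per_patient = cells_per_patient, fluorophores = panel,
                abundance_means = am, field_px = 96, cell_radius_px = c(8, 12),
                seed = seed)
}

# one small calibrated cohort with features, shared across tests
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- small_config(seed = 11)
    ch <- default_channel_table()
    co <- generate_cohort(cfg, ch)
    model <- fit_calibration(co$references)
    calibrated <- lapply(co$blocks, calibrate_block, model = model)
    features <- extract_cohort_features(calibrated, co$labels)
    .fixture_env$cohort <- list(cfg = cfg, channels = ch, cohort = co,
                                model = model, calibrated = calibrated,
                                features = features)
  }
  .fixture_env$cohort
}

# feature table simulated directly at the feature level (fast classifier tests)
gaussian_table <- function(n_per_class = 30, delta = 2, p_noise = 4, seed = 1,
                           n_patients_per_class = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- rep(c("neg", "pos"), each = n_per_class)
  df <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    patient_id = paste0(cls, "_p",
                        rep_len(seq_len(n_patients_per_class), n_per_class)),
    group_label = cls)
  df$shifted <- stats::rnorm(n) + delta * (cls == "pos")
  for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- stats::rnorm(n)
  feature_table(df)
}
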