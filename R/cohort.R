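## Synthetic multispectral cohort generator. Emulates everything upstream of
## feature extraction: fluorophore mixtures with group-specific abundance
## shifts, per-patient random effects, Poisson shot noise, dead/saturated
## pixels, radial illumination falloff, background fluorescence, reference
## frames, and ground-truth masks.

#' Configuration for a synthetic patient cohort
#'
#' Defaults emulate the scale of the study cohort this pipeline was built
#' around: three diagnostic groups (ATN, graft rejection, IFTA) of ten
#' patients each, with 5--7 analyzable cells per patient (about 160 cells in
#' total), imaged in 34 spectral channels. The group signal is carried by
#' shifted NADH-like/FAD-like abundances; a per-patient log-normal multiplier
#' creates the within-patient correlation that real cohorts have.
#'
#' @param groups Character vector of group names.
#' @param patients_per_group Patients per group.
#' @param cells_per_patient Integer range `c(lo, hi)`; the per-patient cell
#'   count is drawn uniformly from it.
#' @param fluorophores Named list of [fluorophore()] objects.
#' @param abundance_means Matrix (groups x fluorophores) of mean abundances.
#' @param abundance_cv Coefficient of variation of per-cell abundances
#'   (log-normal).
#' @param patient_effect_sd SD (log scale) of the per-patient multiplicative
#'   random effect applied to all abundances.
#' @param illumination_gradient Relative falloff of illumination at the field
#'   corner (0 = flat field).
#' @param background_level Mean background fluorescence (counts) per channel.
#' @param dead_pixel_rate,saturated_pixel_rate Per-pixel defect probabilities.
#' @param full_well Sensor saturation level (counts).
#' @param photon_gain Counts produced per unit abundance x channel response.
#' @param field_px Field side length in pixels (square field).
#' @param cell_radius_px Range of ellipse semi-axis lengths (pixels).
#' @param texture_sd Relative SD of the smooth intra-cell intensity texture.
#' @param seed Integer seed fixing all randomness of [generate_cohort()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("ATN", "REJECTION", "IFTA"),
                          patients_per_group = 10,
                          cells_per_patient = c(5, 7),
                          fluorophores = default_fluorophores(),
                          abundance_means = NULL,
                          abundance_cv = 0.2,
                          patient_effect_sd = 0.15,
                          illumination_gradient = 0.3,
                          background_level = 20,
                          dead_pixel_rate = 5e-4,
                          saturated_pixel_rate = 5e-4,
                          full_well = 65535,
                          photon_gain = 2000,
                          field_px = 256,
                          cell_radius_px = c(10, 16),
                          texture_sd = 0.10,
                          seed = 1L) {
  if (is.null(abundance_means)) {
    # group-specific metabolic shifts: rejection raised NADH-like, IFTA raised
    # FAD-like, relative to ATN
    abundance_means <- rbind(c(1.0, 0.6), c(1.4, 0.5), c(1.0, 0.9))
    rownames(abundance_means) <- c("ATN", "REJECTION", "IFTA")
    colnames(abundance_means) <- names(fluorophores)
    abundance_means <- abundance_means[seq_along(groups), , drop = FALSE]
    rownames(abundance_means) <- groups
  }
  stopifnot(identical(rownames(abundance_means), groups),
            identical(colnames(abundance_means), names(fluorophores)),
            all(abundance_means >= 0),
            dead_pixel_rate >= 0, dead_pixel_rate <= 1,
            saturated_pixel_rate >= 0, saturated_pixel_rate <= 1,
            full_well > background_level,
            length(cells_per_patient) == 2,
            cells_per_patient[1] <= cells_per_patient[2])
  structure(
    list(groups = groups, patients_per_group = patients_per_group,
         cells_per_patient = as.integer(cells_per_patient),
         fluorophores = fluorophores, abundance_means = abundance_means,
         abundance_cv = abundance_cv, patient_effect_sd = patient_effect_sd,
         illumination_gradient = illumination_gradient,
         background_level = background_level,
         dead_pixel_rate = dead_pixel_rate,
         saturated_pixel_rate = saturated_pixel_rate,
         full_well = full_well, photon_gain = photon_gain,
         field_px = as.integer(field_px),
         cell_radius_px = cell_radius_px, texture_sd = texture_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Radial illumination field
#'
#' Quadratic falloff from the field center, identical across channels:
#' `1 - gradient * (r / r_corner)^2`, so the corner is dimmed by `gradient`
#' relative to the center.
#'
#' @param nr,nc Field size in pixels.
#' @param gradient Relative corner falloff in [0, 1).
#' @return `nr` x `nc` matrix of relative illumination in (0, 1].
#' @export
illumination_field <- function(nr, nc, gradient) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r2 <- (y - cy)^2 + (x - cx)^2
  1 - gradient * r2 / max(r2)
}

# log-normal with mean `mean` and coefficient of variation `cv`
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# place n non-overlapping ellipses in an nr x nc field; returns a data.frame
# of centers/axes/angles or errors after bounded retries
place_cells <- function(n, nr, nc, radius_range, margin = 3, max_tries = 400) {
  placed <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0))
  for (k in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      rmax <- max(a, b)
      cy <- stats::runif(1, rmax + 2, nr - rmax - 1)
      cx <- stats::runif(1, rmax + 2, nc - rmax - 1)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >
              pmax(placed$a, placed$b) + rmax + margin)) {
        placed[k, ] <- c(cy, cx, a, b, stats::runif(1, 0, pi))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("field too crowded: could not place cell ", k,
                  " after ", max_tries, " tries")
  }
  placed
}

# label image from ellipse parameters (1..n, 0 background)
rasterize_cells <- function(placed, nr, nc) {
  label <- matrix(0L, nr, nc)
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(placed))) {
    p <- placed[k, ]
    dy <- y - p$cy; dx <- x - p$cx
    u <- (dx * cos(p$theta) + dy * sin(p$theta)) / p$a
    v <- (-dx * sin(p$theta) + dy * cos(p$theta)) / p$b
    label[u^2 + v^2 <= 1] <- k
  }
  label
}

# smooth multiplicative texture field, mean ~1, relative SD `sd`
texture_field <- function(nr, nc, sd) {
  if (sd <= 0) return(matrix(1, nr, nc))
  z <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma = 3)
  z <- (z - mean(z)) / stats::sd(z)
  pmax(1 + sd * z, 0.2)
}

apply_sensor_defects <- function(counts, cfg) {
  counts <- pmin(counts, cfg$full_well)
  n <- length(counts)
  if (cfg$dead_pixel_rate > 0) {
    counts[stats::runif(n) < cfg$dead_pixel_rate] <- 0
  }
  if (cfg$saturated_pixel_rate > 0) {
    counts[stats::runif(n) < cfg$saturated_pixel_rate] <- cfg$full_well
  }
  counts
}

#' Render one synthetic multispectral data block
#'
#' Expected pixel intensity in channel c is
#' `illum(x, y) * (texture(x, y) * gain * sum_f abundance_f * response(f, c) +
#' background)` inside a cell and `illum * background` outside; the observed
#' count is Poisson-distributed, then clipped to the full well, with dead and
#' saturated pixels overwritten. Masks match the rendered cell supports
#' exactly. Uses the current RNG state; seed at the caller for determinism.
#'
#' @param cfg A [cohort_config()].
#' @param patient_id,group Patient metadata for the block.
#' @param n_cells Number of cells to place.
#' @param channels A `channel_table`.
#' @param sample_id Block identifier (defaults to `<patient_id>_b1`).
#' @return List with elements `block` (raw `data_block`), `label` (mask label
#'   image), and `truth` (per-cell abundance matrix, illumination field, cell
#'   geometry).
#' @export
render_block <- function(cfg, patient_id, group, n_cells, channels,
                         sample_id = paste0(patient_id, "_b1")) {
  nr <- cfg$field_px; nc <- cfg$field_px
  fl <- cfg$fluorophores
  illum <- illumination_field(nr, nc, cfg$illumination_gradient)
  patient_mult <- exp(stats::rnorm(1, -cfg$patient_effect_sd^2 / 2,
                                   cfg$patient_effect_sd))
  placed <- place_cells(n_cells, nr, nc, cfg$cell_radius_px)
  label <- rasterize_cells(placed, nr, nc)
  texture <- texture_field(nr, nc, cfg$texture_sd)

  abund <- matrix(0, n_cells, length(fl),
                  dimnames = list(NULL, names(fl)))
  for (f in names(fl)) {
    abund[, f] <- rlnorm_cv(n_cells, cfg$abundance_means[group, f] * patient_mult,
                            cfg$abundance_cv)
  }

  resp <- vapply(names(fl), function(nm) channel_response_vector(fl[[nm]], channels),
                 numeric(nrow(channels)))  # channels x fluors
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = nrow(channels))

  # per-pixel fluorophore signal (before channel response): cell-dependent
  cellsig <- matrix(0, nr * nc, length(fl))
  for (k in seq_len(n_cells)) {
    px <- which(label == k)
    for (j in seq_along(fl)) cellsig[px, j] <- abund[k, j]
  }
  cellsig <- cellsig * as.vector(texture) * cfg$photon_gain

  images <- list()
  for (i in seq_len(nrow(channels))) {
    expected <- as.vector(illum) *
      (cellsig %*% resp[i, ] + cfg$background_level)
    counts <- stats::rpois(nr * nc, expected)
    counts <- apply_sensor_defects(counts, cfg)
    images[[channels$channel_id[i]]] <- matrix(as.numeric(counts), nr, nc)
  }

  bf_expected <- as.vector(illum) * 5000 * ifelse(as.vector(label) > 0, 0.7, 1)
  brightfield <- matrix(as.numeric(pmin(stats::rpois(nr * nc, bf_expected),
                                        cfg$full_well)), nr, nc)

  block <- data_block(sample_id, patient_id, group, channels, images,
                      brightfield, calibrated = FALSE)
  truth <- list(abundances = abund, illumination = illum, cells = placed,
                patient_multiplier = patient_mult)
  list(block = block, label = label, truth = truth)
}

#' Simulated spectrofluorometer reference spectrum of the calibration fluid
#'
#' The calibration fluid is a fixed NADH + FAD mixture; its reference spectrum
#' across the channel table is the response of that two-fluorophore mixture,
#' using molar proportions 30:18 (NADH:FAD), plus a small broadband pedestal
#' (5% of the peak response). The pedestal reflects that the real fluid
#' fluoresces measurably in every channel -- far tails of the emission bands
#' are broader than the Gaussian model -- and keeps every channel
#' calibratable.
#'
#' @param cfg A [cohort_config()] (provides the fluorophore panel).
#' @param channels A `channel_table`.
#' @param pedestal Broadband floor as a fraction of the peak response.
#' @return Named positive numeric vector of reference values per channel.
#' @export
reference_spectrum <- function(cfg, channels, pedestal = 0.05) {
  fl <- cfg$fluorophores
  conc <- c(30, 18)[seq_along(fl)]  # uM NADH : uM FAD
  names(conc) <- names(fl)
  s <- mixed_spectrum(fl, as.list(conc), channels)
  pmax(s, pedestal * max(s))
}

#' Render synthetic reference frames (water + calibration fluid)
#'
#' Water frames carry only background under the illumination field; the
#' calibration-fluid frames add `gain * R_c` where `R_c` is the simulated
#' spectrofluorometer reference spectrum of the NADH+FAD mixture. The
#' reference values stored in the set are `R_c` exactly.
#'
#' @param cfg A [cohort_config()].
#' @param channels A `channel_table`.
#' @param gain Counts per reference unit in the calibration frames.
#' @return Object of class `reference_set` with `background_images`,
#'   `calibration_images`, `reference_values`, `dark_offset`, `gain`.
#' @export
render_reference_set <- function(cfg, channels, gain = 500) {
  nr <- cfg$field_px; nc <- cfg$field_px
  illum <- illumination_field(nr, nc, cfg$illumination_gradient)
  rv <- reference_spectrum(cfg, channels)
  background <- list(); calibration <- list()
  for (id in channels$channel_id) {
    bg_expected <- as.vector(illum) * cfg$background_level
    cal_expected <- as.vector(illum) * (cfg$background_level + gain * rv[[id]])
    background[[id]] <- matrix(as.numeric(
      apply_sensor_defects(stats::rpois(nr * nc, bg_expected), cfg)), nr, nc)
    calibration[[id]] <- matrix(as.numeric(
      apply_sensor_defects(stats::rpois(nr * nc, cal_expected), cfg)), nr, nc)
  }
  structure(list(background_images = background,
                 calibration_images = calibration,
                 reference_values = rv, dark_offset = 0, gain = gain),
            class = "reference_set")
}

#' Channels informative about group membership, from the generative model
#'
#' A channel is informative when the expected (noise-free, illumination-free)
#' cell spectrum differs between some pair of groups by more than `margin`
#' relative to the across-group mean. Deterministic in the configuration; no
#' data are used.
#'
#' @param cfg A [cohort_config()].
#' @param channels A `channel_table`.
#' @param margin Relative difference threshold (default 0.10).
#' @return Character vector of informative channel ids.
#' @export
informative_channels <- function(cfg, channels, margin = 0.10) {
  spectra <- vapply(cfg$groups, function(g) {
    mixed_spectrum(cfg$fluorophores,
                   as.list(cfg$abundance_means[g, ]), channels)
  }, numeric(nrow(channels)))
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = nrow(channels))
  spread <- apply(spectra, 1, function(v) {
    m <- mean(v)
    if (m <= 0) 0 else (max(v) - min(v)) / m
  })
  channels$channel_id[spread > margin]
}

#' Generate a full synthetic cohort
#'
#' Draws one data block per patient (all of a patient's cells in one field),
#' a shared reference set, and ground truth. Fully deterministic under
#' `cfg$seed`. With `dir` given, writes the on-disk cohort layout:
#' `patients/<id>/` block directories (TIFFs + manifest + `masks.tif`),
#' `references/`, `channel_table.csv`, `labels.csv` and `ground_truth.json`.
#'
#' @param cfg A [cohort_config()].
#' @param channels A `channel_table` (default [default_channel_table()]).
#' @param dir Optional output directory.
#' @return List with `blocks` (list of `data_block`), `labels` (list of mask
#'   label images, parallel to `blocks`), `references` (a `reference_set`),
#'   `truth` (per-block ground truth + `informative_channels`), and
#'   `cells` (data.frame: cell_id, sample_id, patient_id, group_label).
#' @export
generate_cohort <- function(cfg, channels = default_channel_table(),
                            dir = NULL) {
  set.seed(cfg$seed)
  references <- render_reference_set(cfg, channels)
  blocks <- list(); labels <- list(); truth <- list()
  cells <- data.frame(cell_id = character(0), sample_id = character(0),
                      patient_id = character(0), group_label = character(0))
  for (g in cfg$groups) {
    for (p in seq_len(cfg$patients_per_group)) {
      patient_id <- sprintf("%s_p%02d", g, p)
      n_cells <- if (cfg$cells_per_patient[1] == cfg$cells_per_patient[2]) {
        cfg$cells_per_patient[1]
      } else {
        sample(cfg$cells_per_patient[1]:cfg$cells_per_patient[2], 1)
      }
      r <- render_block(cfg, patient_id, g, n_cells, channels)
      sid <- r$block$sample_id
      blocks[[sid]] <- r$block
      labels[[sid]] <- r$label
      truth[[sid]] <- r$truth
      cells <- rbind(cells, data.frame(
        cell_id = paste0(sid, "_", sprintf("cell%03d", seq_len(n_cells))),
        sample_id = sid, patient_id = patient_id, group_label = g))
    }
  }
  truth$informative_channels <- informative_channels(cfg, channels)
  cohort <- list(blocks = blocks, labels = labels, references = references,
                 truth = truth, cells = cells, config = cfg,
                 channels = channels)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort directory
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "patients"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$blocks)) {
    bdir <- file.path(dir, "patients", sid)
    write_data_block(cohort$blocks[[sid]], bdir)
    write_masks(cohort$labels[[sid]], file.path(bdir, "masks.tif"))
  }
  write_reference_set(cohort$references, file.path(dir, "references"))
  write_channel_table(cohort$channels, file.path(dir, "channel_table.csv"))
  utils::write.csv(cohort$cells, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  gt <- list(informative_channels = cohort$truth$informative_channels,
             abundances = lapply(
               cohort$truth[names(cohort$blocks)],
               function(t) as.data.frame(t$abundances)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return List with `blocks`, `labels`, `references`, `cells`, `channels`.
#' @export
read_cohort <- function(dir) {
  channels <- read_channel_table(file.path(dir, "channel_table.csv"))
  cells <- utils::read.csv(file.path(dir, "labels.csv"),
                           stringsAsFactors = FALSE)
  sids <- unique(cells$sample_id)
  blocks <- list(); labels <- list()
  for (sid in sids) {
    bdir <- file.path(dir, "patients", sid)
    blocks[[sid]] <- read_data_block(bdir)
    labels[[sid]] <- attr(read_masks(file.path(bdir, "masks.tif")),
                          "label_image")
  }
  references <- read_reference_set(file.path(dir, "references"))
  list(blocks = blocks, labels = labels, references = references,
       cells = cells, channels = channels)
}

#' Write a reference set (water + calibration TIFFs + reference values)
#' @param refs A `reference_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(refs$background_images)) {
    write_image_tiff(refs$background_images[[id]],
                     file.path(dir, paste0(id, "_water.tif")))
    write_image_tiff(refs$calibration_images[[id]],
                     file.path(dir, paste0(id, "_calibration.tif")))
  }
  jsonlite::write_json(list(reference_values = as.list(refs$reference_values),
                            dark_offset = refs$dark_offset),
                       file.path(dir, "reference_values.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference set written by [write_reference_set()]
#' @param dir Reference directory.
#' @return A `reference_set`.
#' @export
read_reference_set <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "reference_values.json"))
  ids <- names(meta$reference_values)
  background <- list(); calibration <- list()
  for (id in ids) {
    background[[id]] <- read_image_tiff(file.path(dir, paste0(id, "_water.tif")))
    calibration[[id]] <- read_image_tiff(file.path(dir, paste0(id, "_calibration.tif")))
  }
  structure(list(background_images = background,
                 calibration_images = calibration,
                 reference_values = unlist(meta$reference_values),
                 dark_offset = meta$dark_offset),
            class = "reference_set")
}
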