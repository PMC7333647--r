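# Fully synthetic radiogenomic cohort generator: genomic/clinical tables,
# survival outcomes, and 3D multi-sequence MR volumes with tumor ROI masks,
# with the statistical structure the downstream analysis assumes.

#' Simulation configuration
#'
#' Defaults emulate the published LGG cohort structure: ~22.8% CIC mutation
#' prevalence, near-containment of CIC within IDH-mutant & 1p/19q-codeleted
#' patients (99.1% / 93.1%), a protective CIC hazard ratio (0.2445), and a
#' baseline hazard matching a wild-type median OS of 1,933 days. Image
#' parameters (shape, spacing, ROI radii, texture contrast) are free
#' parameters of the generator, not claims about real gliomas; mutant tumors
#' are generated larger and more heterogeneous than wild-type ones.
#'
#' @param n_patients cohort size (>= 2).
#' @param cic_prevalence,p_idh_given_cic,p_codel_given_cic fractions in
#'   `[0, 1]`.
#' @param cic_rate_in_codel_idh target CIC rate among IDH-mutant codeleted
#'   patients (fixes, via Bayes, how often non-CIC patients carry the
#'   IDH+codel genotype).
#' @param p_idh_other IDH mutation rate among patients outside the CIC or
#'   IDH+codel groups.
#' @param hazard_ratio_cic multiplicative hazard for CIC-mutant patients.
#' @param baseline_hazard events/day for CIC wild-type.
#' @param censor_rate expected fraction of censored patients.
#' @param image_shape voxel triple (each >= 8).
#' @param voxel_spacing mm triple.
#' @param roi_radius_by_label ROI radius (mm) for wild-type and mutant.
#' @param texture_contrast effect size of the label-dependent texture
#'   difference (0 switches the texture difference off).
#' @param noise_sd additive Gaussian intensity noise.
#' @param seed master seed; all randomness is derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 120L,
                       cic_prevalence = 0.228,
                       p_idh_given_cic = 0.991,
                       p_codel_given_cic = 0.931,
                       cic_rate_in_codel_idh = 0.659,
                       p_idh_other = 0.72,
                       hazard_ratio_cic = 0.2445,
                       baseline_hazard = log(2) / 1933,
                       censor_rate = 0.6,
                       image_shape = c(40L, 40L, 32L),
                       voxel_spacing = c(1, 1, 1),
                       roi_radius_by_label = c(6, 9),
                       texture_contrast = 1,
                       noise_sd = 0.05,
                       seed = 1L) {
  if (n_patients < 2L) stop_cfg("n_patients must be >= 2")
  for (nm in c("cic_prevalence", "p_idh_given_cic", "p_codel_given_cic",
               "cic_rate_in_codel_idh", "p_idh_other", "censor_rate")) {
    check_fraction(get(nm), nm)
  }
  if (hazard_ratio_cic <= 0) stop_cfg("hazard_ratio_cic must be > 0")
  if (baseline_hazard <= 0) stop_cfg("baseline_hazard must be > 0")
  if (any(image_shape < 8L)) stop_cfg("image_shape dims must be >= 8")
  if (any(voxel_spacing <= 0)) stop_cfg("voxel_spacing must be > 0")
  if (length(roi_radius_by_label) != 2L || any(roi_radius_by_label <= 0)) {
    stop_cfg("roi_radius_by_label must be two positive radii (wt, mutant)")
  }
  ext <- image_shape * voxel_spacing
  if (2 * max(roi_radius_by_label) >= 0.9 * min(ext)) {
    stop_cfg("ROI radius exceeds image extent")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cic_prevalence = cic_prevalence,
    p_idh_given_cic = p_idh_given_cic,
    p_codel_given_cic = p_codel_given_cic,
    cic_rate_in_codel_idh = cic_rate_in_codel_idh,
    p_idh_other = p_idh_other,
    hazard_ratio_cic = hazard_ratio_cic,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    image_shape = as.integer(image_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    roi_radius_by_label = as.numeric(roi_radius_by_label),
    texture_contrast = texture_contrast,
    noise_sd = noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# Arm definitions used for the synthetic SEG table (positions are synthetic
# but in a realistic bp range).
SYNTH_ARMS <- data.frame(
  arm = c("1p", "19q", "7p"),
  chrom = c("1", "19", "7"),
  start = c(1L, 32000001L, 1L),
  end = c(120000000L, 59000000L, 60000000L),
  stringsAsFactors = FALSE)

#' Generate the synthetic genomic/clinical cohort
#'
#' Draws CIC labels at the configured prevalence; conditional on CIC, IDH and
#' codeletion labels at their configured conditional rates; among non-CIC
#' patients the IDH+codel genotype frequency is set by Bayes' rule so the CIC
#' rate within IDH-mutant codeleted patients matches
#' `cic_rate_in_codel_idh`. Variant rows use qualifying classifications
#' (missense/frameshift/nonsense) for true mutations and silent/other rows as
#' background noise on other genes; deleted arms receive segment means well
#' below -0.2 and intact arms means above -0.1, so genomic calling recovers
#' the ground truth exactly. Survival is exponential proportional hazards
#' with independent exponential censoring tuned to `censor_rate`, rounded up
#' to whole days.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (clinical data.frame), `variants` (MAF-like),
#'   `segments` (SEG-like, 1-based inclusive), `truth` (ground-truth labels
#'   and hazards).
#' @export
generate_genomic_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  set.seed(derive_seed(config$seed, "genomic", 0L))
  pid <- sprintf("SYN-%04d", seq_len(n))

  cic <- stats::rbinom(n, 1, config$cic_prevalence)
  idh <- integer(n); codel <- integer(n)
  p_joint_cic <- config$p_idh_given_cic * config$p_codel_given_cic
  r <- config$cic_rate_in_codel_idh
  # P(idh & codel | ~cic) from Bayes so that P(cic | idh & codel) ~= r
  q <- if (r > 0 && config$cic_prevalence < 1) {
    min(1, config$cic_prevalence * p_joint_cic * (1 / r - 1) /
          (1 - config$cic_prevalence))
  } else {
    0
  }
  for (i in seq_len(n)) {
    if (cic[i] == 1L) {
      idh[i] <- stats::rbinom(1, 1, config$p_idh_given_cic)
      codel[i] <- stats::rbinom(1, 1, config$p_codel_given_cic)
    } else if (stats::runif(1) < q) {
      idh[i] <- 1L; codel[i] <- 1L
    } else {
      idh[i] <- stats::rbinom(1, 1, config$p_idh_other)
      codel[i] <- 0L
    }
  }
  fubp1 <- stats::rbinom(n, 1, ifelse(cic == 1L, 0.31, 0.026))

  age <- pmax(18L, as.integer(round(stats::rnorm(n, 44, 12) + 4 * cic)))
  gender <- ifelse(stats::runif(n) < 0.5, "female", "male")
  grade <- ifelse(stats::runif(n) < ifelse(cic == 1L, 0.58, 0.45), "G2", "G3")

  hazard <- config$baseline_hazard * config$hazard_ratio_cic^cic
  t_event <- stats::rexp(n, hazard)
  cens_rate <- config$baseline_hazard * config$censor_rate /
    max(1e-12, 1 - config$censor_rate)
  t_cens <- if (config$censor_rate > 0) {
    stats::rexp(n, cens_rate)
  } else {
    rep(Inf, n)
  }
  os_days <- pmax(1, ceiling(pmin(t_event, t_cens)))
  os_event <- as.integer(t_event <= t_cens)

  variants <- synth_variants(pid, cic, idh, fubp1, config)
  segments <- synth_segments(pid, codel, config)

  cohort <- data.frame(
    patient_id = pid, age = age, gender = gender, grade = grade,
    cic = cic, idh = idh, codel = codel, fubp1 = fubp1,
    histology_2016 = classify_2016(idh, codel),
    os_days = os_days, os_event = os_event,
    stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid, cic = cic, idh = idh, codel = codel,
                      fubp1 = fubp1, true_hazard = hazard,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, variants = variants, segments = segments,
       truth = truth)
}

# One qualifying classification at fixed mixture weights.
sample_qualifying <- function(k) {
  sample(QUALIFYING_CLASSES, k, replace = TRUE, prob = c(0.60, 0.25, 0.15))
}

synth_variants <- function(pid, cic, idh, fubp1, config) {
  n <- length(pid)
  rows <- list()
  add <- function(patients, gene, classes) {
    if (length(patients)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = patients, gene = gene, variant_classification = classes,
        stringsAsFactors = FALSE)
    }
  }
  mut_cic <- pid[cic == 1L]
  add(mut_cic, "CIC", sample_qualifying(length(mut_cic)))
  idh_gene <- ifelse(stats::runif(sum(idh)) < 0.9, "IDH1", "IDH2")
  add(pid[idh == 1L], idh_gene, sample_qualifying(sum(idh)))
  add(pid[fubp1 == 1L], "FUBP1", sample_qualifying(sum(fubp1)))
  # background genes: mix of qualifying and non-qualifying records
  for (bg in list(list("TP53", 0.40), list("ATRX", 0.30), list("TTN", 0.15),
                  list("PIK3CA", 0.09), list("EGFR", 0.05))) {
    hit <- stats::runif(n) < bg[[2]]
    add(pid[hit], bg[[1]], sample_qualifying(sum(hit)))
  }
  noise <- stats::runif(n) < 0.2
  add(pid[noise], "TTN",
      sample(c("silent", "other"), sum(noise), replace = TRUE))
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$gene), , drop = FALSE]
}

synth_segments <- function(pid, codel, config) {
  rows <- list()
  for (i in seq_along(pid)) {
    for (a in seq_len(nrow(SYNTH_ARMS))) {
      arm <- SYNTH_ARMS[a, ]
      deleted <- arm$arm %in% c("1p", "19q") && codel[i] == 1L
      # split the arm in two segments half the time to exercise
      # length-weighted aggregation; both pieces stay on the same side of
      # the calling threshold so ground truth is recovered exactly
      split <- stats::runif(1) < 0.5
      mean_draw <- function(k) {
        if (deleted) stats::runif(k, -0.7, -0.3) else stats::runif(k, -0.1, 0.1)
      }
      if (split) {
        mid <- floor((arm$start + arm$end) / 2)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid[i], chrom = arm$chrom, arm = arm$arm,
          start = c(arm$start, mid + 1L), end = c(mid, arm$end),
          seg_mean = round(mean_draw(2L), 4), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid[i], chrom = arm$chrom, arm = arm$arm,
          start = arm$start, end = arm$end,
          seg_mean = round(mean_draw(1L), 4), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Squared normalized ellipsoid distance of every voxel from a center (mm).
ellipsoid_dist2 <- function(shape, spacing, center_mm, semi_mm) {
  x <- (seq_len(shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(shape[3]) - 0.5) * spacing[3]
  dx2 <- ((x - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((y - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((z - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate the synthetic image cohort
#'
#' One anatomy per patient: brain ellipsoid with a smooth intensity field, a
#' spherical tumor ROI whose radius depends on the label, and label-dependent
#' internal texture — mutant tumors get multi-scale random blobs (high
#' intensity-zone fragmentation), wild-type tumors a compact dark necrotic
#' core with a bright rim. The four sequences share the anatomy through
#' affine contrast transfer functions plus independent noise, so they are
#' co-registered by construction. Deterministic given the master seed
#' (per-patient sub-seeds from [derive_seed()]).
#'
#' @param config a [sim_config()].
#' @param labels 0/1 vector of length `n_patients` (CIC status).
#' @return named list (one element per patient) of lists with `T1pre`,
#'   `T1post`, `T2`, `FLAIR` ([image_volume()]s), `mask` (0/1 array) and
#'   `brain` (0/1 array).
#' @export
generate_image_cohort <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  if (length(labels) != config$n_patients) {
    stop_cfg("labels length must equal n_patients")
  }
  shape <- config$image_shape
  sp <- config$voxel_spacing
  ext <- shape * sp
  out <- list()
  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, "image", i))
    lab <- labels[i]
    r_mm <- config$roi_radius_by_label[lab + 1L]

    brain <- ellipsoid_dist2(shape, sp, ext / 2, 0.45 * ext) <= 1
    # smooth anatomical field: a few random low-frequency cosines
    anat <- array(0, shape)
    xg <- (seq_len(shape[1]) - 0.5) / shape[1]
    yg <- (seq_len(shape[2]) - 0.5) / shape[2]
    zg <- (seq_len(shape[3]) - 0.5) / shape[3]
    for (k in 1:3) {
      fr <- stats::runif(3, 0.5, 2); ph <- stats::runif(3, 0, 2 * pi)
      anat <- anat + 0.15 * outer(outer(cos(2 * pi * fr[1] * xg + ph[1]),
                                        cos(2 * pi * fr[2] * yg + ph[2])),
                                  cos(2 * pi * fr[3] * zg + ph[3]))
    }
    anat <- (1 + anat) * brain

    # tumor center jittered around the brain center
    ctr <- ext / 2 + stats::runif(3, -0.08, 0.08) * ext
    d2 <- ellipsoid_dist2(shape, sp, ctr, rep(r_mm, 3))
    mask <- (d2 <= 1) & brain
    if (!any(mask)) stop_cfg("ROI radius produced an empty mask")

    tumor <- array(0, shape)
    cc <- config$texture_contrast
    if (lab == 1L) {
      # heterogeneous: multi-scale Gaussian blobs inside the ROI
      n_blob <- 25L
      for (b in seq_len(n_blob)) {
        u <- stats::runif(3, -0.8, 0.8)
        bc <- ctr + u * r_mm
        sig <- stats::runif(1, 0.8, 2.5)
        amp <- cc * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.2)
        bd2 <- ellipsoid_dist2(shape, sp, bc, rep(sig, 3))
        tumor <- tumor + amp * exp(-bd2 / 2)
      }
    } else {
      # compact: dark necrotic core, bright rim
      dn <- sqrt(d2)
      tumor <- cc * (-0.9 * exp(-(dn / 0.45)^2) +
                       0.9 * exp(-((dn - 0.85) / 0.18)^2))
    }
    tumor[!mask] <- 0

    transfer <- list(T1pre = c(off = 0.00, gain = 0.90, w = 0.80),
                     T1post = c(off = 0.10, gain = 0.85, w = 1.10),
                     T2 = c(off = 0.20, gain = 0.60, w = 1.00),
                     FLAIR = c(off = 0.15, gain = 0.75, w = 0.95))
    pat <- list()
    for (sq in names(transfer)) {
      tf <- transfer[[sq]]
      v <- tf[["off"]] * brain + tf[["gain"]] * anat + tf[["w"]] * tumor +
        config$noise_sd * array(stats::rnorm(prod(shape)), shape)
      pat[[sq]] <- image_volume(v, sp)
    }
    pat$mask <- array(as.integer(mask), shape)
    pat$brain <- array(as.integer(brain), shape)
    out[[sprintf("SYN-%04d", i)]] <- pat
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort CSV, MAF-like and SEG-like TSVs, ground-truth JSON, and
#' (optionally) one NIfTI volume per sequence per patient plus the ROI mask.
#'
#' @param genomic result of [generate_genomic_cohort()].
#' @param images result of [generate_image_cohort()], or `NULL` to skip.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(genomic, images = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    variants = file.path(dir, "variants.tsv"),
    segments = file.path(dir, "segments.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(genomic$cohort, paths["cohort"], row.names = FALSE)
  utils::write.table(genomic$variants, paths["variants"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(genomic$segments, paths["segments"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(genomic$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (pid in names(images)) {
      pat <- images[[pid]]
      for (sq in c("T1pre", "T1post", "T2", "FLAIR")) {
        p <- file.path(img_dir, paste0(pid, "_", sq, ".nii.gz"))
        write_nifti(pat[[sq]], p)
        paths <- c(paths, p)
      }
      p <- file.path(img_dir, paste0(pid, "_mask.nii.gz"))
      write_nifti(pat$mask, p, spacing = pat$T1pre$spacing,
                  datatype = "uint8")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
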