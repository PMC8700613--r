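# Synthetic resting-state cohort generator.
#
# The stated world mirrors the emulated study design: two groups of 43
# subjects, 197 volumes at TR = 3 s (7 discarded downstream), an
# atlas-style block parcellation, lower signal complexity in designated
# regions of group 2, and one neuropsychological measure linked to one
# region's measured entropy. Voxel signals follow a MIX-style regularity
# model: x_t = (1 - lambda) * sin(2*pi*f*t*TR + phase) + lambda * eps_t,
# whose AAPE increases monotonically with lambda.

# One-time characterization of the lambda -> AAPE map at the defaults
# (N = 190, m = 4, K = 0.5, f = 0.05 Hz, TR = 3 s), used to convert the
# stated subject-level effect size d into a lambda shift:
#   AAPE_GRAD : d(mean AAPE)/d(lambda) around lambda_base
#   AAPE_VOXSD: sd of voxel AAPE at fixed lambda (independent noise draws)
# Measured by scripts in the methods vignette; see there for the curve.
AAPE_CALIB <- list(lambda_base = 0.30, grad = 2.9, vox_sd = 0.073)

#' Simulation configuration
#'
#' Assembles the parameters of the synthetic cohort. Defaults emulate the
#' study design the package targets: `n_per_group = 43`, `n_volumes = 197`
#' at `tr = 3` seconds, 20 block regions on a 12x12x12 grid, 4 affected
#' regions where group 2 ("SCD") has more regular signals, and the CDRSB
#' measure linked to the first affected region's measured entropy with
#' generating correlation `link_r = 0.6`. Covariate and measure
#' distributions follow the published demographics of the emulated cohorts.
#'
#' The group difference is injected on the mixing weight lambda. With
#' between-subject sd `lambda_sd`, the shift `delta_lambda` realizing a
#' subject-level standardized effect `effect_d` on regional mean AAPE is
#' `effect_d * sqrt(lambda_sd^2 + vox_sd^2 / (V * grad^2))` with `V` voxels
#' per region and (`grad`, `vox_sd`) the measured slope and voxel-level
#' noise of the lambda -> AAPE map.
#'
#' @param n_per_group subjects per group.
#' @param grid_dim 3D grid dimensions.
#' @param n_rois number of cubic block regions (placed on a 3x3x3 tiling).
#' @param n_volumes acquired volumes per subject (before discarding).
#' @param tr repetition time, seconds.
#' @param n_discard leading volumes the analysis discards.
#' @param affected_rois region ids with a group difference.
#' @param lambda_base baseline mixing weight (0 = pure sinusoid,
#'   1 = pure noise).
#' @param lambda_sd between-subject sd of lambda.
#' @param effect_d standardized group difference on regional mean AAPE in
#'   affected regions.
#' @param freq sinusoid frequency, Hz (within the typical BOLD band).
#' @param noise_model `"mix"` (Gaussian noise, default) or `"ar1"`
#'   (AR(1) noise, unit marginal variance, coefficient 0.4).
#' @param link_roi,link_measure,link_r the linked (region, measure) pair in
#'   group 2 and its generating correlation (0 disables the link).
#' @param m,K entropy parameters used when the generator computes profiles.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_group = 43L, grid_dim = c(12L, 12L, 12L),
                       n_rois = 20L, n_volumes = 197L, tr = 3,
                       n_discard = 7L, affected_rois = c(3L, 7L, 12L, 18L),
                       lambda_base = AAPE_CALIB$lambda_base,
                       lambda_sd = 0.05, effect_d = 1.2, freq = 0.05,
                       noise_model = c("mix", "ar1"),
                       link_roi = 3L, link_measure = "CDRSB", link_r = 0.6,
                       m = 4L, K = 0.5) {
  noise_model <- match.arg(noise_model)
  cfg <- list(n_per_group = as.integer(n_per_group),
              grid_dim = as.integer(grid_dim), n_rois = as.integer(n_rois),
              n_volumes = as.integer(n_volumes), tr = tr,
              n_discard = as.integer(n_discard),
              affected_rois = as.integer(affected_rois),
              lambda_base = lambda_base, lambda_sd = lambda_sd,
              effect_d = effect_d, freq = freq, noise_model = noise_model,
              link_roi = as.integer(link_roi), link_measure = link_measure,
              link_r = link_r, m = as.integer(m), K = K)
  if (cfg$n_per_group < 2L) stop("n_per_group must be >= 2")
  if (length(cfg$grid_dim) != 3L || any(cfg$grid_dim < 3L))
    stop("grid_dim must be three dimensions >= 3")
  blocks <- prod(cfg$grid_dim %/% 3L)
  if (cfg$n_rois < 1L || cfg$n_rois > blocks)
    stop("n_rois must be in 1..", blocks, " for this grid")
  if (cfg$lambda_base < 0 || cfg$lambda_base > 1 ||
      cfg$lambda_sd < 0)
    stop("lambda_base must lie in [0, 1] and lambda_sd must be >= 0")
  if (!all(cfg$affected_rois %in% seq_len(cfg$n_rois)))
    stop("affected_rois must be a subset of 1..n_rois")
  if (!(cfg$link_roi %in% seq_len(cfg$n_rois)))
    stop("link_roi must be one of 1..n_rois")
  if (abs(cfg$link_r) > 1) stop("link_r must lie in [-1, 1]")
  if (cfg$n_volumes <= cfg$n_discard + cfg$m)
    stop("n_volumes must exceed n_discard + m")
  class(cfg) <- "sim_config"
  cfg
}

# Published demographics of the emulated groups (mean, sd) / counts.
COHORT_PARAMS <- list(
  NA_grp = list(age = c(73.57, 3.27), male = 17 / 43,
                education = c(16.33, 2.35), meanFD = c(0.20, 0.08),
                ADAS13 = c(9.26, 5.32), ADAS_Word = c(2.88, 1.94),
                GDS = c(1.12, 1.89), CDRSB = c(0.15, 0.55),
                MMSE = c(28.98, 1.14), PACC_DSST = c(-0.18, 4.06),
                PACC_LogTMTB = c(-0.14, 3.64)),
  SCD = list(age = c(75.48, 5.66), male = 14 / 43,
             education = c(16.37, 2.90), meanFD = c(0.20, 0.08),
             ADAS13 = c(7.91, 4.58), ADAS_Word = c(2.00, 1.48),
             GDS = c(1.30, 1.12), CDRSB = c(0.21, 0.48),
             MMSE = c(29.14, 0.97), PACC_DSST = c(0.53, 2.90),
             PACC_LogTMTB = c(0.34, 2.74))
)

#' Generate one synthetic voxel series
#'
#' MIX-style regularity model: `(1 - lambda) * sin(2*pi*freq*t*tr + phase)
#' + lambda * eps_t`, with `eps_t` i.i.d. standard normal (or an AR(1)
#' process with unit marginal variance). Expected AAPE increases
#' monotonically with `lambda`.
#'
#' @param lambda mixing weight in \[0, 1\].
#' @param n_volumes series length.
#' @param seed optional seed (uses and restores a private RNG state).
#' @param tr sampling interval, seconds.
#' @param freq sinusoid frequency, Hz.
#' @param phase sinusoid phase, radians.
#' @param noise_model `"mix"` or `"ar1"`.
#' @return numeric series of length `n_volumes`.
#' @export
generate_voxel_series <- function(lambda, n_volumes = 197L, seed = NULL,
                                  tr = 3, freq = 0.05, phase = 0,
                                  noise_model = c("mix", "ar1")) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1], got ", lambda)
  gen <- function() {
    eps <- rnorm(n_volumes)
    if (noise_model == "ar1") {
      phi <- 0.4
      eps <- as.vector(stats::filter(eps * sqrt(1 - phi^2), phi,
                                     method = "recursive"))
    }
    tt <- seq_len(n_volumes)
    (1 - lambda) * sin(2 * pi * freq * tt * tr + phase) + lambda * eps
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Block parcellation: 3x3x3 cubes tiled over the grid, first n_rois kept.
make_block_atlas <- function(grid_dim, n_rois) {
  nb <- grid_dim %/% 3L
  atlas <- array(0L, dim = grid_dim)
  lab <- 0L
  for (bz in seq_len(nb[3L])) for (by in seq_len(nb[2L]))
    for (bx in seq_len(nb[1L])) {
      lab <- lab + 1L
      if (lab > n_rois) return(atlas)
      atlas[(bx - 1L) * 3L + 1:3, (by - 1L) * 3L + 1:3,
            (bz - 1L) * 3L + 1:3] <- lab
    }
  atlas
}

lambda_delta <- function(cfg, vox_per_roi) {
  cfg$effect_d * sqrt(cfg$lambda_sd^2 +
    AAPE_CALIB$vox_sd^2 / (vox_per_roi * AAPE_CALIB$grad^2))
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject covariates, per-(subject, region) regularity weights
#' lambda, and 4D images; computes each subject's regional entropy profile
#' with the standard pipeline (discard, voxelwise AAPE, regional means);
#' then generates neuropsychological measures, linking `link_measure` in
#' group 2 to the measured entropy of `link_roi` (residual, standardized)
#' with generating correlation `link_r`. Group 2 receives lower lambda
#' (more regular signal, lower AAPE) in the affected regions only. PACC
#' component columns are z-scored across the cohort.
#'
#' Fully deterministic given (`config`, `seed`).
#'
#' @param config a [sim_config].
#' @param seed integer seed.
#' @param keep_images keep the per-subject 4D arrays in the result (needed
#'   by [write_cohort]; off by default to save memory).
#' @return object of class `synthetic_cohort`: list with `config`, `seed`,
#'   `atlas` (3D integer array), `roi_names`, `cohort` (subject table),
#'   `profiles` (long entropy profiles), `lambda` (subjects x regions
#'   matrix of true weights), and `images` (named list, if kept).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L,
                            keep_images = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, generate_cohort_impl(config, seed, keep_images))
}

generate_cohort_impl <- function(cfg, seed, keep_images) {
  atlas <- make_block_atlas(cfg$grid_dim, cfg$n_rois)
  roi_names <- sprintf("ROI%03d", seq_len(cfg$n_rois))
  vox_idx <- lapply(seq_len(cfg$n_rois), function(l) which(atlas == l))
  vox_per_roi <- lengths(vox_idx)
  delta <- lambda_delta(cfg, min(vox_per_roi))
  groups <- rep(c("NA", "SCD"), each = cfg$n_per_group)
  n <- length(groups)
  sids <- sprintf("sub-%03d", seq_len(n))
  acfg <- aape_config(m = cfg$m, K = cfg$K)

  # covariates
  draw2 <- function(field) {
    out <- numeric(n)
    for (g in c("NA", "SCD")) {
      p <- COHORT_PARAMS[[if (g == "NA") "NA_grp" else "SCD"]][[field]]
      out[groups == g] <- rnorm(cfg$n_per_group, p[1L], p[2L])
    }
    out
  }
  male_p <- ifelse(groups == "NA", COHORT_PARAMS$NA_grp$male,
                   COHORT_PARAMS$SCD$male)
  cohort <- data.frame(
    subject_id = sids, group = groups,
    age = draw2("age"),
    sex = rbinom(n, 1L, male_p),
    education = draw2("education"),
    meanFD = pmax(0.02, draw2("meanFD")),
    ADAS13 = pmax(0, draw2("ADAS13")),
    ADAS_Word = pmax(0, draw2("ADAS_Word")),
    GDS = pmax(0, draw2("GDS")),
    stringsAsFactors = FALSE)

  # per-(subject, region) regularity and images -> profiles
  lam_mean <- matrix(cfg$lambda_base, n, cfg$n_rois)
  aff <- cfg$affected_rois
  lam_mean[groups == "SCD", aff] <- cfg$lambda_base - delta
  lam <- lam_mean + matrix(rnorm(n * cfg$n_rois, 0, cfg$lambda_sd),
                           n, cfg$n_rois)
  lam[] <- pmin(1, pmax(0, lam))

  tt <- seq_len(cfg$n_volumes)
  profiles <- vector("list", n)
  images <- if (keep_images) stats::setNames(vector("list", n), sids)
  base_t <- 2 * pi * cfg$freq * cfg$tr * tt
  for (s in seq_len(n)) {
    img_mat <- matrix(0, prod(cfg$grid_dim), cfg$n_volumes)
    for (r in seq_len(cfg$n_rois)) {
      v <- vox_idx[[r]]; nv <- length(v)
      phase <- runif(nv, 0, 2 * pi)
      S <- sin(outer(phase, base_t, `+`))
      E <- matrix(rnorm(nv * cfg$n_volumes), nv)
      if (cfg$noise_model == "ar1") {
        phi <- 0.4
        E <- t(apply(E, 1L, function(e)
          as.vector(stats::filter(e * sqrt(1 - phi^2), phi,
                                  method = "recursive"))))
      }
      img_mat[v, ] <- (1 - lam[s, r]) * S + lam[s, r] * E
    }
    img <- array(img_mat, dim = c(cfg$grid_dim, cfg$n_volumes))
    profiles[[s]] <- subject_profile(img, atlas, subject_id = sids[s],
                                     config = acfg,
                                     n_discard = cfg$n_discard,
                                     roi_names = roi_names)
    if (keep_images) images[[s]] <- img
  }
  profiles <- do.call(rbind, profiles)

  # measures: noise at published moments; linked pair in group 2 tied to
  # the measured entropy residual of link_roi
  scd <- groups == "SCD"
  ent_link <- profiles$mean_aape[profiles$roi_id == cfg$link_roi]
  # link to the covariate-residualized entropy (what the prediction stage
  # analyzes); small cohorts without enough df fall back to centering
  covmat <- as.matrix(cohort[scd, c("age", "sex", "education", "meanFD",
                                    "ADAS13", "ADAS_Word", "GDS")])
  z_link <- if (sum(scd) > ncol(covmat) + 2L)
    as.vector(scale(residualize(ent_link[scd], covmat)))
  else as.vector(scale(ent_link[scd]))
  for (mname in c("CDRSB", "MMSE", "PACC_DSST", "PACC_LogTMTB")) {
    z <- rnorm(n)
    if (mname == cfg$link_measure && cfg$link_r != 0)
      z[scd] <- cfg$link_r * z_link +
        sqrt(1 - cfg$link_r^2) * rnorm(sum(scd))
    val <- numeric(n)
    for (g in c("NA", "SCD")) {
      p <- COHORT_PARAMS[[if (g == "NA") "NA_grp" else "SCD"]][[mname]]
      val[groups == g] <- p[1L] + p[2L] * z[groups == g]
    }
    # deliberately not clamped to clinical ranges: the linkage must stay
    # linear-Gaussian so generating correlations are exact
    cohort[[mname]] <- val
  }
  for (pc in c("PACC_DSST", "PACC_LogTMTB"))
    cohort[[pc]] <- as.vector(scale(cohort[[pc]]))

  structure(list(config = cfg, seed = seed, atlas = atlas,
                 roi_names = roi_names, cohort = cohort,
                 profiles = profiles, lambda = lam,
                 images = if (keep_images) images),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d + %d subjects, %d regions on ",
                     "%s grid, %d volumes, seed %d\n"),
              sum(x$cohort$group == "NA"), sum(x$cohort$group == "SCD"),
              x$config$n_rois, paste(x$config$grid_dim, collapse = "x"),
              x$config$n_volumes, x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one 4D NIfTI per subject, the atlas NIfTI, the cohort TSV, the
#' profiles TSV, and a JSON manifest holding the seed, the full
#' configuration, and per-file MD5 checksums, sufficient to regenerate and
#' verify the cohort.
#'
#' @param cohort a `synthetic_cohort` generated with `keep_images = TRUE`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$images))
    stop("cohort holds no images; regenerate with keep_images = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  files <- character(0)
  for (sid in names(cohort$images)) {
    f <- file.path(dir, paste0(sid, "_bold.nii.gz"))
    write_nifti(cohort$images[[sid]], f,
                pixdim = c(1, 1, 1, cfg$tr), datatype = "float32")
    files <- c(files, f)
  }
  fa <- file.path(dir, "atlas.nii.gz")
  write_nifti(cohort$atlas, fa, pixdim = c(1, 1, 1), datatype = "int16")
  ft <- file.path(dir, "cohort.tsv")
  utils::write.table(cohort$cohort, ft, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fp <- file.path(dir, "profiles.tsv")
  write_profiles(cohort$profiles, fp)
  files <- c(files, fa, ft, fp)
  manifest <- list(seed = cohort$seed,
                   config = unclass(cfg),
                   files = basename(files),
                   md5 = as.list(tools::md5sum(files)))
  names(manifest$md5) <- basename(files)
  fm <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
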