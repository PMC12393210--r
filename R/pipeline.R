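#' Pipeline configuration
#'
#' A single list describing every stage of the synthetic
#' acquisition-to-concentration pipeline; it round-trips losslessly
#' through JSON ([write_config()] / [read_config()]). Defaults mirror the
#' reference protocol at full scale; use [make_fixture()] for ready-made
#' full-scale and reduced-scale configurations.
#'
#' @param name configuration name.
#' @param grid simulation/reconstruction grid: `n` (output matrix) and
#'   `fov` (mm).
#' @param phantom arguments for [phantom_spec()] (list; empty = defaults).
#' @param fields `tx_variation` and `seed` for [generate_coil_fields()].
#' @param quant quantitative-acquisition settings: `n_projections`,
#'   `n_samples`, `nominal_resolution` (mm), `te`, `tr`, `nominal_fa`,
#'   `readout_duration`, `noise_rel` (noise SD as a fraction of the RMS
#'   noiseless sample magnitude), `zerofill`, `filter`.
#' @param b1 B1+-map acquisition settings: `n_projections`, `n_samples`,
#'   `nominal_resolution`, `noise_rel`, `zerofill`, `gauss_sigma`.
#' @param quantification `vial_erosion_mm`, `voi_erosion_mm` (phantom VOI
#'   margin; default one effective-resolution width, 2.1 x nominal).
#' @param seed global seed; per-stage seeds are derived as
#'   `seed * 100 + stage_index` (documented counter scheme, keeps
#'   stage-level reproducibility under partial re-runs).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(name = "paper_replica",
                            grid = list(n = 160, fov = 400),
                            phantom = list(),
                            fields = list(tx_variation = 0.4, seed = 11),
                            quant = list(n_projections = 10000,
                                         n_samples = 256,
                                         nominal_resolution = 5,
                                         te = 1, tr = 150, nominal_fa = 61,
                                         readout_duration = 5,
                                         noise_rel = 0.02,
                                         zerofill = 2, filter = "hamming"),
                            b1 = list(n_projections = 1020,
                                      n_samples = 256,
                                      nominal_resolution = 20,
                                      noise_rel = 0.02,
                                      zerofill = 8, gauss_sigma = 20),
                            quantification = list(
                              vial_erosion_mm = 5,
                              voi_erosion_mm = 2.1 * 5),
                            seed = 1L) {
  cfg <- list(name = name, grid = grid, phantom = phantom, fields = fields,
              quant = quant, b1 = b1, quantification = quantification,
              seed = as.integer(seed))
  # consistency: zerofilled matrices must agree with the shared output grid
  qn <- grid$fov / quant$nominal_resolution * quant$zerofill
  bn <- grid$fov / b1$nominal_resolution * b1$zerofill
  if (abs(qn - grid$n) > 1e-9 || abs(bn - grid$n) > 1e-9)
    stop(sprintf(paste0(
      "inconsistent config: quantitative (%g) and B1 (%g) output matrices",
      " must both equal grid n = %d"), qn, bn, grid$n))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$phantom <- as.list(cfg$phantom)
  do.call(pipeline_config, cfg)
}

#' Ready-made pipeline fixtures
#'
#' * `paper_replica`: the full reference protocol -- (400 mm)^3 FOV,
#'   quantitative image with 10000 spokes x 256 samples at 5 mm nominal
#'   resolution (Hamming, zerofill 2, output 160^3 at 2.5 mm), B1+ map
#'   with 1020 spokes at 20 mm (Gauss sigma 20 mm, zerofill 8).
#' * `tiny`: a seconds-scale reduction for tests and CI -- nominal matrix
#'   32 (quantitative image 500 spokes x 64 samples at 12.5 mm nominal,
#'   zerofill 2 -> 64^3 output at 6.25 mm), B1+ map 200 spokes x 32
#'   samples at 50 mm (zerofill 8; same output grid). Filter/zerofill
#'   semantics unchanged; the nominal resolution stays well below the
#'   38 mm vial diameter so reference-vial calibration remains
#'   well-posed (it is not at coarser scales).
#'
#' Both share the phantom geometry, 40% transmit variation and a noise
#' level of 2% of the RMS k-space sample (an SNR regime comparable to 7 T
#' sodium imaging).
#'
#' @param name `"tiny"` or `"paper_replica"`.
#' @param seed global seed.
#' @return a [pipeline_config()].
#' @export
make_fixture <- function(name = c("tiny", "paper_replica"), seed = 1L) {
  name <- match.arg(name)
  if (name == "paper_replica")
    return(pipeline_config(name = name, seed = seed))
  pipeline_config(
    name = "tiny",
    grid = list(n = 64, fov = 400),
    fields = list(tx_variation = 0.4, seed = 11),
    quant = list(n_projections = 500, n_samples = 64,
                 nominal_resolution = 12.5, te = 1, tr = 150,
                 nominal_fa = 61, readout_duration = 5, noise_rel = 0.02,
                 zerofill = 2, filter = "hamming"),
    b1 = list(n_projections = 200, n_samples = 32,
              nominal_resolution = 50, noise_rel = 0.02,
              zerofill = 8, gauss_sigma = 50),
    quantification = list(vial_erosion_mm = 5,
                          voi_erosion_mm = 2.1 * 12.5),
    seed = seed)
}

rel_noise_sd <- function(samples, rel) {
  if (rel <= 0) return(0)
  rel * sqrt(mean(Mod(samples)^2))
}

add_kspace_noise <- function(data, rel, seed) {
  sd <- rel_noise_sd(data$samples, rel)
  if (sd == 0) return(data)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  nv <- length(data$samples)
  data$samples <- data$samples + sd *
    (array(stats::rnorm(nv), dim = dim(data$samples)) +
       1i * array(stats::rnorm(nv), dim = dim(data$samples)))
  data$params$noise_sd <- sd
  data
}

stage_seed <- function(config, index) config$seed * 100L + as.integer(index)

#' Run the full synthetic quantification pipeline
#'
#' Executes phantom -> coil fields -> trajectories -> k-space simulation
#' (quantitative + dual flip angle) -> gridding reconstruction -> B1+ map
#' -> T1/B1+/B1- corrections -> reference-vial calibration ->
#' concentration map -> evaluation, writing every intermediate artifact
#' (NIfTI volumes, RDS k-space, JSON fits/reports, TSV tables) under
#' `outdir` together with a manifest recording the configuration, its
#' hash, per-stage seeds, timing and output-file checksums. Corrections
#' are evaluated as three chains (uncorrected, B1+ only, B1+ and B1-; the
#' compartmental T1 factor is applied in all three) so that their VOI CVs
#' can be compared.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param verbose log stage progress to the console.
#' @return (invisibly) a list with every stage result: `maps`, `fields`,
#'   `masks`, `recon`, `fa_map`, `corrected`, `fits`, `concentration`
#'   (per chain), `report`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = interactive()) {
  t_all <- proc.time()[3]
  stages <- list()
  files <- character()
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(path) files <<- c(files, path)
  stamp <- function(name, t0)
    stages[[name]] <<- list(stage = name, seconds = round(proc.time()[3] - t0, 3))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  out <- function(f) if (is.null(outdir)) NULL else file.path(outdir, f)
  wn <- function(grid, f, datatype = "float64") {
    if (!is.null(outdir)) {
      write_nifti(grid, out(f), datatype = datatype); emit(out(f))
    }
  }

  grid <- empty_grid(config$grid$n, config$grid$fov)
  spec <- do.call(phantom_spec, config$phantom)

  t0 <- proc.time()[3]; say("stage 1/9: phantom")
  maps <- generate_phantom(spec, grid)
  wn(maps$concentration, "phantom_concentration.nii.gz")
  wn(with_values(grid, ifelse(is.na(maps$t1$values), 0, maps$t1$values)),
     "phantom_t1.nii.gz")
  stamp("phantom", t0)

  t0 <- proc.time()[3]; say("stage 2/9: coil fields")
  fields <- generate_coil_fields(grid, config$fields$tx_variation,
                                 seed = config$fields$seed)
  rx_sos <- rx_sos_field(fields)
  wn(fields$tx_scale, "tx_scale.nii.gz")
  wn(rx_sos, "rx_sos.nii.gz")
  stamp("fields", t0)

  t0 <- proc.time()[3]; say("stage 3/9: trajectories")
  q <- config$quant
  qp <- acq_params(te = q$te, tr = q$tr, nominal_fa = q$nominal_fa,
                   readout_duration = q$readout_duration,
                   n_projections = q$n_projections, n_samples = q$n_samples,
                   nominal_resolution = q$nominal_resolution,
                   fov = config$grid$fov, seed = stage_seed(config, 4))
  traj_q <- trajectory_for(qp)
  b <- config$b1
  bp <- b1_map_params(n_projections = b$n_projections,
                      n_samples = b$n_samples,
                      nominal_resolution = b$nominal_resolution,
                      fov = config$grid$fov, seed = stage_seed(config, 5))
  traj_b <- trajectory_for(bp$fa45)
  if (!is.null(outdir)) {
    export_trajectory(traj_q, out("traj_quant")); emit(out("traj_quant_directions.tsv"))
  }
  stamp("trajectory", t0)

  t0 <- proc.time()[3]; say("stage 4/9: simulate quantitative k-space")
  ks_q <- simulate_kspace(maps, fields, traj_q, qp)
  ks_q <- add_kspace_noise(ks_q, q$noise_rel, stage_seed(config, 4))
  if (!is.null(outdir)) { saveRDS(ks_q, out("kspace_quant.rds")); emit(out("kspace_quant.rds")) }
  stamp("simulate_quant", t0)

  t0 <- proc.time()[3]; say("stage 5/9: simulate dual-flip-angle k-space")
  ks_b <- simulate_dual_fa(maps, fields, traj_b, bp)
  ks_b$fa45 <- add_kspace_noise(ks_b$fa45, b$noise_rel, stage_seed(config, 5))
  ks_b$fa90 <- add_kspace_noise(ks_b$fa90, b$noise_rel, stage_seed(config, 6))
  if (!is.null(outdir)) { saveRDS(ks_b, out("kspace_dualfa.rds")); emit(out("kspace_dualfa.rds")) }
  stamp("simulate_dualfa", t0)

  t0 <- proc.time()[3]; say("stage 6/9: reconstruct quantitative image")
  rs_q <- recon_settings(filter = q$filter, zerofill = q$zerofill)
  rec_q <- adjoint_recon(ks_q, rs_q)
  img <- rec_q$image
  wn(img, "image_quant_sos.nii.gz")
  stamp("recon_quant", t0)

  t0 <- proc.time()[3]; say("stage 7/9: B1+ map")
  rs_b <- recon_settings(filter = "gauss", gauss_sigma = b$gauss_sigma,
                         zerofill = b$zerofill)
  img45 <- adjoint_recon(ks_b$fa45, rs_b)$image
  img90 <- adjoint_recon(ks_b$fa90, rs_b)$image
  fa_map <- dual_fa_map(img45, img90)
  wn(with_values(grid, ifelse(is.na(fa_map$rel_b1$values), 0,
                              fa_map$rel_b1$values)), "rel_b1.nii.gz")
  stamp("b1map", t0)

  t0 <- proc.time()[3]; say("stage 8/9: corrections + calibration")
  vial_masks <- vial_voi_masks(img, spec,
                               erosion_mm = config$quantification$vial_erosion_mm)
  union_mask <- with_values(grid, array(
    Reduce(`|`, lapply(vial_masks, function(m) m$values)), grid$shape))
  chains <- list(
    uncorrected = list(fa = NULL, rx = NULL),
    b1plus = list(fa = fa_map, rx = NULL),
    full = list(fa = fa_map, rx = rx_sos))
  corrected <- list(); fits <- list(); conc <- list()
  for (nm in names(chains)) {
    ch <- chains[[nm]]
    corrected[[nm]] <- apply_corrections(
      img, fa_map = ch$fa, rx_sos = ch$rx, t1_map = maps$t1,
      nominal_fa = q$nominal_fa, tr = q$tr, norm_mask = union_mask)
    fits[[nm]] <- calibrate(corrected[[nm]], vial_masks,
                            spec$vial_concentrations)
    conc[[nm]] <- to_concentration(corrected[[nm]], fits[[nm]])
  }
  wn(with_values(grid, ifelse(is.na(conc$full$values), 0, conc$full$values)),
     "concentration_full.nii.gz")
  if (!is.null(outdir)) {
    write_calibration(fits$full, out("calibration_full.json"))
    emit(out("calibration_full.json"))
  }
  stamp("quantify", t0)

  t0 <- proc.time()[3]; say("stage 9/9: evaluation")
  vois <- c(list(phantom = phantom_voi(
    grid, spec, erosion_mm = config$quantification$voi_erosion_mm)),
    stats::setNames(vial_masks, paste0("vial", 1:4)))
  report <- lapply(conc, eval_report, vois = vois)
  if (!is.null(outdir)) {
    jsonlite::write_json(
      list(config = unclass(config),
           r_squared = lapply(fits, `[[`, "r_squared"),
           report = lapply(report, unclass)),
      out("evaluation.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(out("evaluation.json"))
    tab <- do.call(rbind, lapply(names(report), function(chain)
      do.call(rbind, lapply(names(report[[chain]]), function(v)
        data.frame(chain = chain, voi = v,
                   mean = report[[chain]][[v]]$mean,
                   sd = report[[chain]][[v]]$sd,
                   cv = report[[chain]][[v]]$cv,
                   n = report[[chain]][[v]]$n)))))
    utils::write.table(tab, out("evaluation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(out("evaluation.tsv"))
  }
  stamp("evaluate", t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("naquant")),
    config = unclass(config),
    config_hash = config_hash(config),
    stage_seeds = stats::setNames(
      as.list(vapply(1:9, stage_seed, config = config, integer(1))),
      names(stages)),
    stages = unname(stages),
    total_seconds = round(proc.time()[3] - t_all, 3),
    outputs = if (is.null(outdir)) list() else
      as.list(tools::md5sum(files[file.exists(files)])))
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(config = config, maps = maps, fields = fields,
                 rx_sos = rx_sos, traj_quant = traj_q, traj_b1 = traj_b,
                 kspace_quant = ks_q, image = img, fa_map = fa_map,
                 vial_masks = vial_masks, corrected = corrected,
                 fits = fits, concentration = conc, vois = vois,
                 report = report, manifest = manifest))
}

#' Stable hash of a pipeline configuration
#' @param config a `pipeline_config`.
#' @return md5 hex digest of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
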