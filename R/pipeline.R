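#' Run configuration for the end-to-end analyses
#'
#' Bundles the synthetic-cohort description and the analysis knobs for
#' [run_power_analysis()] and [run_coupling_analysis()].
#'
#' @param synthetic a [synthetic_config()] describing each subject's
#'   recording, or NULL with `input_dirs` pointing at fixture directories
#'   readable by [read_recording()]. Exactly one of the two must be given.
#' @param input_dirs character vector of fixture directories (one subject
#'   each), or NULL when simulating.
#' @param n_subjects number of synthetic subjects.
#' @param band analysis band in Hz.
#' @param n_bins phase bins for transfer entropy.
#' @param f_center lag-defining centre frequency in Hz.
#' @param epoch_len_s epoch length in seconds.
#' @param epochs_per_state maximum non-overlapping epochs analysed per
#'   state and subject; epoch-level results are averaged within
#'   subject-state before any group statistic.
#' @param voxel_fraction voxel subsampling fraction for spectral estimation.
#' @param n_perm permutations for the voxelwise randomization test.
#' @param tfce a [tfce_params()].
#' @param lag_control whether to run the seed-based lag-map control in the
#'   coupling analysis.
#' @param seed master RNG seed, recorded in every output.
#' @param out_dir optional output directory; when given, tables, maps and a
#'   hashed manifest are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), input_dirs = NULL,
                       n_subjects = 10, band = c(0.01, 0.08), n_bins = 8,
                       f_center = 0.03, epoch_len_s = 120,
                       epochs_per_state = 1, voxel_fraction = 0.05,
                       n_perm = 5000, tfce = tfce_params(),
                       lag_control = TRUE, seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) == is.null(input_dirs))
    stop("exactly one of `synthetic` and `input_dirs` must be given")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(synthetic = synthetic, input_dirs = input_dirs,
                 n_subjects = as.integer(n_subjects), band = band,
                 n_bins = as.integer(n_bins), f_center = f_center,
                 epoch_len_s = epoch_len_s,
                 epochs_per_state = as.integer(epochs_per_state),
                 voxel_fraction = voxel_fraction,
                 n_perm = as.integer(n_perm), tfce = tfce,
                 lag_control = isTRUE(lag_control),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Recognised keys mirror the [run_config()] arguments; a `synthetic` block
#' is passed to [synthetic_config()], a `tfce` block to [tfce_params()].
#'
#' @param path file ending in .json, .yaml or .yml.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$synthetic))
    args$synthetic <- do.call(synthetic_config, as_config_args(raw$synthetic))
  if (!is.null(raw$tfce)) args$tfce <- do.call(tfce_params, raw$tfce)
  do.call(run_config, args)
}

as_config_args <- function(x) {
  for (nm in c("kappa", "power_scale")) {
    if (!is.null(x[[nm]]))
      x[[nm]] <- lapply(x[[nm]], function(m)
        if (nm == "kappa") matrix(unlist(m), 3, 3,
                                  dimnames = list(c("ELEC", "BLOOD", "WATER"),
                                                  c("ELEC", "BLOOD", "WATER")))
        else unlist(m))
  }
  if (!is.null(x$nuisance)) x$nuisance <- unlist(x$nuisance)
  x
}

# Load or simulate the cohort: a list of multimodal_recording, one per
# subject, with per-subject seeds derived from the master seed.
load_cohort <- function(cfg) {
  if (!is.null(cfg$input_dirs)) return(lapply(cfg$input_dirs, read_recording))
  lapply(seq_len(cfg$n_subjects), function(s) {
    sc <- cfg$synthetic
    sc$seed <- cfg$seed + 7919L * s
    simulate_recording(sc, seed = sc$seed)
  })
}

# Flatten the in-mask BOLD voxels of a recording into a time x voxels matrix.
bold_matrix <- function(rec) {
  d <- dim(rec$bold)
  t(matrix(rec$bold, prod(d[1:3]), d[4])[which(rec$mask), , drop = FALSE])
}

#' Infraslow power analysis across arousal states
#'
#' For every subject and state epoch, estimates Morlet time-frequency power
#' for the BOLD (random voxel subsample), EEG (all electrodes) and NIRS
#' modalities, integrates the 0.01-0.08 Hz band, and contrasts wakefulness
#' against the pooled sleep states with a two-tailed Wilcoxon rank-sum test
#' per modality under FDR correction.
#'
#' @param cfg a [run_config()].
#' @return list with `band_powers` (data.frame: subject, state, modality,
#'   band_power), `spectra` (matrix subject-state rows x frequencies per
#'   modality), `group` (per-state median/IQR curves per modality),
#'   `contrasts` (data.frame: modality, z, p, p_adj), `grid`, `seed`.
#' @export
run_power_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- load_cohort(cfg)
  grid <- freq_grid(range = c(0.01, min(5, 0.49 * cohort[[1]]$fs)))
  rows <- list(); spec_rows <- list()
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]
    vox <- subsample_voxels(rec$mask, cfg$voxel_fraction,
                            seed = cfg$seed + 31L * s)
    bm <- bold_matrix(rec)
    vcols <- match(vox, which(rec$mask))
    epochs <- extract_state_epochs(rec$hypnogram,
                                   cbind(bm[, vcols, drop = FALSE],
                                         t(rec$eeg), t(rec$nirs)),
                                   rec$fs, cfg$epoch_len_s,
                                   max_per_state = cfg$epochs_per_state)
    nv <- length(vcols); ne <- nrow(rec$eeg)
    for (ep in epochs) {
      sig <- ep$signals
      mods <- list(BOLD = sig[, seq_len(nv), drop = FALSE],
                   EEG = sig[, nv + seq_len(ne), drop = FALSE],
                   NIRS = sig[, nv + ne + 1:3, drop = FALSE])
      for (m in names(mods)) {
        ps <- modality_spectrum(mods[[m]], grid, rec$fs)
        bp <- band_power(ps, cfg$band, grid = grid)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, state = ep$state, modality = m,
          band_power = as.numeric(bp))
        spec_rows[[length(spec_rows) + 1L]] <-
          list(subject = s, state = ep$state, modality = m, spectrum = ps)
      }
    }
  }
  band_powers <- do.call(rbind, rows)

  # epoch-level estimates are averaged within subject-state before the
  # group comparison, so subjects are the statistical units
  subj_bp <- stats::aggregate(band_power ~ subject + state + modality,
                              band_powers, mean)
  contrasts <- do.call(rbind, lapply(unique(subj_bp$modality), function(m) {
    d <- subj_bp[subj_bp$modality == m, ]
    awake <- d$band_power[d$state == "AWAKE"]
    sleep <- d$band_power[d$state %in% c("N1", "N2")]
    w <- wilcoxon_ranksum(awake, sleep)
    data.frame(modality = m, z = w$z, p = w$p,
               n_awake = w$n1, n_sleep = w$n2)
  }))
  contrasts$p_adj <- fdr_adjust(contrasts$p)

  spectra <- lapply(split(spec_rows, vapply(spec_rows, `[[`, "", "modality")),
    function(lst) {
      m <- t(vapply(lst, `[[`, numeric(length(grid$frequencies)), "spectrum"))
      rownames(m) <- vapply(lst, function(x)
        paste0("s", x$subject, "_", x$state), "")
      attr(m, "states") <- vapply(lst, `[[`, "", "state")
      m
    })
  group <- lapply(spectra, function(m) group_spectrum(m, attr(m, "states")))

  res <- list(band_powers = band_powers, spectra = spectra, group = group,
              contrasts = contrasts, grid = grid, seed = cfg$seed)
  if (!is.null(cfg$out_dir)) write_power_outputs(res, cfg)
  res
}

#' Directed coupling analysis across arousal states
#'
#' Band-limits every modality of every subject with the zero-phase FIR
#' filter, extracts one epoch per state, computes voxelwise delta TE maps
#' for the BOLD-EEG and BOLD-H2O pairs and the EEG-H2O electrode topography,
#' aggregates them over the whole brain and the 9 atlas ROIs, contrasts
#' states with Wilcoxon/FDR on the aggregates and with the TFCE
#' randomization test on the voxel maps, and runs the seed-lag control.
#'
#' @param cfg a [run_config()].
#' @return list with `roi_table` (subject x state x pair ROI aggregates),
#'   `whole_brain` (subset of roi_table), `maps` (per subject-state voxel
#'   maps), `topography` (per-electrode EEG-H2O delta TE),
#'   `contrasts` (Wilcoxon/FDR on whole-brain delta TE per pair and state
#'   contrast), `voxel_contrast` (TFCE permutation result for BOLD-EEG,
#'   first state pair), `lag_control` (per subject-state lag-vs-TE
#'   correlation), `lag` (samples), `seed`.
#' @export
run_coupling_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- load_cohort(cfg)
  fs <- cohort[[1]]$fs
  lag <- default_lag(cfg$f_center, fs)
  spec <- fir_spec(cfg$band, fs)
  taps <- design_fir(spec)
  mask <- cohort[[1]]$mask
  atlas <- cohort[[1]]$atlas
  frontal_label <- 3L  # atlas label order: caudate, cerebellum, frontal, ...

  roi_rows <- list(); maps <- list(); topo_rows <- list(); lag_rows <- list()
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]
    bm <- filter_band(bold_matrix(rec), taps)
    em <- filter_band(t(rec$eeg), taps)
    wm <- filter_band(as.numeric(rec$nirs["H2O", ]), taps)
    epochs <- extract_state_epochs(rec$hypnogram, cbind(bm, em, wm),
                                   fs, cfg$epoch_len_s,
                                   max_per_state = cfg$epochs_per_state)
    nv <- ncol(bm); ne <- ncol(em)
    ep_count <- list()
    for (ep in epochs) {
      sig <- ep$signals
      tm <- pairwise_te_map(sig[, seq_len(nv), drop = FALSE],
                            sig[, nv + seq_len(ne), drop = FALSE],
                            sig[, nv + ne + 1L],
                            lag = lag, n_bins = cfg$n_bins)
      ep_count[[ep$state]] <- (ep_count[[ep$state]] %||% 0L) + 1L
      key <- paste0("s", s, "_", ep$state, "_e", ep_count[[ep$state]])
      maps[[key]] <- tm
      for (pair in c("bold_eeg", "bold_h2o")) {
        agg <- aggregate_te(tm[[pair]], atlas, mask)
        agg$subject <- s; agg$state <- ep$state; agg$pair <- pair
        roi_rows[[length(roi_rows) + 1L]] <- agg
      }
      topo_rows[[length(topo_rows) + 1L]] <- data.frame(
        subject = s, state = ep$state,
        electrode = seq_len(ne), delta_te = tm$eeg_h2o$delta_te)
      if (cfg$lag_control) {
        seed_cols <- which(atlas[which(mask)] == frontal_label)
        xl <- xcorr_lag_map(sig[, seq_len(nv), drop = FALSE], seed_cols, fs,
                            cfg$f_center, te_map = tm$bold_eeg$delta_te,
                            perm_seed = cfg$seed + 13L * s)
        lag_rows[[length(lag_rows) + 1L]] <- data.frame(
          subject = s, state = ep$state,
          rho = xl$te_correlation$rho, p = xl$te_correlation$p)
      }
    }
  }
  roi_table <- do.call(rbind, roi_rows)
  # epoch-level aggregates averaged within subject-state: subjects are the
  # statistical units in the group contrasts
  whole_brain <- stats::aggregate(
    delta_te ~ subject + state + pair,
    roi_table[roi_table$roi == "whole_brain", ], mean)

  states_present <- unique(whole_brain$state)
  state_pairs <- if (length(states_present) >= 2)
    combn(states_present, 2, simplify = FALSE) else list()
  contrasts <- do.call(rbind, lapply(state_pairs, function(sp) {
    do.call(rbind, lapply(unique(whole_brain$pair), function(pr) {
      d <- whole_brain[whole_brain$pair == pr, ]
      w <- wilcoxon_ranksum(d$delta_te[d$state == sp[1]],
                            d$delta_te[d$state == sp[2]])
      data.frame(pair = pr, contrast = paste(sp, collapse = "-"),
                 z = w$z, p = w$p, n1 = w$n1, n2 = w$n2)
    }))
  }))
  if (!is.null(contrasts)) contrasts$p_adj <- fdr_adjust(contrasts$p)

  voxel_contrast <- NULL
  if (length(state_pairs) >= 1) {
    sp <- state_pairs[[1]]
    # subject-level maps: epoch maps averaged within subject
    subj_maps <- function(state) {
      keys <- grep(paste0("_", state, "_e"), names(maps), value = TRUE)
      subj <- sub("^s(\\d+)_.*$", "\\1", keys)
      lapply(split(keys, subj), function(ks) {
        v <- rowMeans(vapply(ks, function(k) maps[[k]]$bold_eeg$delta_te,
                             numeric(sum(mask))))
        m <- array(NA_real_, dim(mask))
        m[which(mask)] <- v
        m
      })
    }
    ka <- subj_maps(sp[1]); kb <- subj_maps(sp[2])
    if (length(ka) >= 2 && length(kb) >= 2)
      voxel_contrast <- permutation_test(ka, kb, mask, n_perm = cfg$n_perm,
                                         params = cfg$tfce, seed = cfg$seed)
  }

  res <- list(roi_table = roi_table, whole_brain = whole_brain, maps = maps,
              topography = do.call(rbind, topo_rows),
              contrasts = contrasts, voxel_contrast = voxel_contrast,
              lag_control = do.call(rbind, lag_rows),
              lag = lag, seed = cfg$seed)
  if (!is.null(cfg$out_dir)) write_coupling_outputs(res, cfg, mask)
  res
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_manifest <- function(paths, cfg, dir) {
  manifest <- list(seed = cfg$seed,
                   files = lapply(paths, function(p)
                     list(path = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
}

write_power_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_tsv(res$band_powers, file.path(cfg$out_dir, "band_powers.tsv")),
    write_tsv(res$contrasts, file.path(cfg$out_dir, "power_contrasts.tsv")))
  jsonlite::write_json(list(seed = cfg$seed,
                            contrasts = res$contrasts),
                       file.path(cfg$out_dir, "power_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(paths, cfg, cfg$out_dir)
  invisible(paths)
}

write_coupling_outputs <- function(res, cfg, mask) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_tsv(res$roi_table, file.path(cfg$out_dir, "te_roi.tsv")),
    write_tsv(res$topography, file.path(cfg$out_dir, "te_topography.tsv")))
  if (!is.null(res$lag_control))
    paths <- c(paths, write_tsv(res$lag_control,
                                file.path(cfg$out_dir, "lag_control.tsv")))
  if (!is.null(res$contrasts))
    paths <- c(paths, write_tsv(res$contrasts,
                                file.path(cfg$out_dir, "te_contrasts.tsv")))
  for (key in names(res$maps)) {
    m <- array(NA_real_, dim(mask))
    m[which(mask)] <- res$maps[[key]]$bold_eeg$delta_te
    p <- file.path(cfg$out_dir, paste0("delta_te_bold_eeg_", key, ".nii"))
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "double"), p)
    paths <- c(paths, p)
  }
  if (!is.null(res$voxel_contrast)) {
    p <- file.path(cfg$out_dir, "voxel_contrast_p.nii")
    RNifti::writeNifti(RNifti::asNifti(res$voxel_contrast$p,
                                       datatype = "double"), p)
    paths <- c(paths, p)
  }
  jsonlite::write_json(list(seed = cfg$seed, lag = res$lag),
                       file.path(cfg$out_dir, "coupling_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(paths, cfg, cfg$out_dir)
  invisible(paths)
}
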