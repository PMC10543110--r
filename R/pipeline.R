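#' Pipeline configuration
#'
#' Collects every knob of the synthetic end-to-end run: domain and surface
#' geometry, acquisition scheme, noise level, permutation and factorization
#' settings, stage toggles and the root seed from which all per-stage seeds
#' are derived (and recorded in the output manifest).
#'
#' @param out_dir output directory.
#' @param seed root integer seed.
#' @param n_subjects number of synthetic subjects.
#' @param grid_shape unfolded surface grid (rows, cols).
#' @param domain_shape voxel-domain intrinsic dimensions (AP, PD, IO).
#' @param geometry `"slab"` or `"curved_shell"`.
#' @param n_dir,n_b0,bvals_shell acquisition scheme layout.
#' @param snr b = 0 signal-to-noise ratio of the simulated data.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param n_perm spin-test permutations.
#' @param k_parcel components for the reported OPNNMF solution.
#' @param k_range k-sweep for the stability analysis.
#' @param n_splits split-half repetitions.
#' @param fit_options NODDI fit options (see [fit_noddi()]); the pipeline
#'   default favours speed over the last decimal.
#' @param stages named logical list toggling `simulate`, `laplace`, `fit`,
#'   `cosine`, `sample`, `average`, `spin`, `classify`, `opnnmf`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "hippmap_out", seed = 1L,
                            n_subjects = 8L, grid_shape = c(32L, 16L),
                            domain_shape = c(10L, 8L, 8L),
                            geometry = "slab",
                            n_dir = 14L, n_b0 = 6L,
                            bvals_shell = c(1000, 2000, 3000),
                            snr = 30, noise_model = "gaussian",
                            n_perm = 500L, k_parcel = 4L, k_range = 2:5,
                            n_splits = 2L,
                            fit_options = list(method = "nm", maxit = 150L,
                                               reltol = 1e-6, n_gl = 16L),
                            stages = NULL) {
  all_stages <- c("simulate", "laplace", "fit", "cosine", "sample",
                  "average", "spin", "classify", "opnnmf")
  st <- stats::setNames(as.list(rep(TRUE, length(all_stages))), all_stages)
  if (!is.null(stages)) st[names(stages)] <- stages
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 domain_shape = as.integer(domain_shape), geometry = geometry,
                 n_dir = as.integer(n_dir), n_b0 = as.integer(n_b0),
                 bvals_shell = bvals_shell, snr = snr,
                 noise_model = noise_model, n_perm = as.integer(n_perm),
                 k_parcel = as.integer(k_parcel), k_range = as.integer(k_range),
                 n_splits = as.integer(n_splits), fit_options = fit_options,
                 stages = st),
            class = "pipeline_config")
}

.stage_seed <- function(config, stage, subject = 0L) {
  offs <- c(simulate = 11L, truth = 23L, spin = 37L, classify = 41L,
            opnnmf = 53L, t1wt2w = 61L)
  (config$seed * 1000L + offs[[stage]] + 7L * subject) %% .Machine$integer.max
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the full analysis chain on synthetic data: ground-truth
#' parameter fields on a voxel domain; multi-shell diffusion simulation;
#' voxel-wise NODDI and DTI fits; Laplace axis fields and cosine-similarity
#' volumes; ribbon-constrained sampling of every metric onto the unfolded
#' midthickness surface; cross-subject averaging; the all-pairs Spearman /
#' torus spin-test report; subfield separability classification; and OPNNMF
#' parcellation with split-half stability. Each stage writes its artifacts
#' under `config$out_dir`, and a JSON manifest records parameters, seeds and
#' file hashes. Disabling a stage makes downstream stages load its cached
#' artifacts from a previous run (aborting with the missing stage named).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  metrics_vol <- c("odi", "ndi", "fa", "md", "t1wt2w", "cs_AP", "cs_PD", "cs_IO")
  subj_ids <- sprintf("sub%03d", seq_len(config$n_subjects))

  scheme <- make_scheme(config$bvals_shell, config$n_dir, config$n_b0)
  write_bvals_bvecs(scheme, file.path(out, "scheme"))
  domain <- make_voxel_domain(config$domain_shape, config$geometry)
  lin <- which(domain$mask)
  dims <- dim(domain$mask)

  # ---- laplace ------------------------------------------------------------
  t0 <- tic()
  if (st$laplace) {
    coords <- laplace_coordinates(domain)
    axes <- gradient_fields(coords)
    for (ax in c("AP", "PD", "IO")) {
      write_volume(coords[[paste0("psi_", ax)]],
                   file.path(out, paste0("psi_", ax, ".nii.gz")),
                   domain$voxel_size_mm)
    }
  } else {
    paths <- file.path(out, paste0("psi_", c("AP", "PD", "IO"), ".nii.gz"))
    if (!all(file.exists(paths))) {
      stop("stage 'laplace' disabled but its artifacts are missing: ",
           paste(basename(paths[!file.exists(paths)]), collapse = ", "))
    }
    coords <- structure(list(psi_AP = read_volume(paths[1]),
                             psi_PD = read_volume(paths[2]),
                             psi_IO = read_volume(paths[3]),
                             domain = domain), class = "laplace_coords")
    axes <- gradient_fields(coords)
  }
  timings["laplace"] <- tic() - t0

  # ---- simulate + fit + cosine + sample, per subject ----------------------
  surface <- .pipeline_surface(domain, config$grid_shape)
  write_surface_csv(surface, file.path(out, "surface"))
  subj_maps <- list()

  t0 <- tic()
  for (s in seq_len(config$n_subjects)) {
    sid <- subj_ids[s]
    map_paths <- file.path(out, sprintf("map_%s_%s.csv", sid, metrics_vol))
    need_sample <- st$sample || !all(file.exists(map_paths))
    if (!need_sample) {
      subj_maps[[sid]] <- stats::setNames(lapply(seq_along(metrics_vol), function(m) {
        mp <- read_unfolded_csv(map_paths[m], metric = metrics_vol[m])
        mp$subject <- sid
        mp
      }), metrics_vol)
      next
    }
    truth <- make_ground_truth_params(domain, axes, jitter_sd = 0.03,
                                      seed = .stage_seed(config, "truth", s))
    sig_path <- file.path(out, sprintf("dwi_%s.nii.gz", sid))
    if (st$simulate) {
      dwi <- simulate_dwi(truth, scheme, snr = config$snr,
                          noise_model = config$noise_model,
                          seed = .stage_seed(config, "simulate", s),
                          n_gl = config$fit_options$n_gl %||% 24)
      write_volume(dwi, sig_path, domain$voxel_size_mm)
    } else {
      if (!file.exists(sig_path)) {
        stop("stage 'simulate' disabled but artifact missing: ", basename(sig_path))
      }
      dwi <- read_volume(sig_path)
    }
    sig <- matrix(dwi, prod(dims), dim(dwi)[4])[lin, , drop = FALSE]

    if (st$fit) {
      nfit <- fit_noddi_map(sig, scheme, config$fit_options)
      dfit <- fit_dti_map(sig, scheme)
      utils::write.csv(cbind(voxel = lin, nfit, dfit[, c("FA", "MD")]),
                       file.path(out, sprintf("fit_%s.csv", sid)),
                       row.names = FALSE)
    } else {
      fp <- file.path(out, sprintf("fit_%s.csv", sid))
      if (!file.exists(fp)) stop("stage 'fit' disabled but artifact missing: ", basename(fp))
      ff <- utils::read.csv(fp)
      nfit <- ff; dfit <- ff
    }

    vol_of <- function(v) { a <- array(NA_real_, dims); a[lin] <- v; a }
    mu_field <- array(NA_real_, c(dims, 3))
    mu_field[, , , 1] <- vol_of(nfit$mu_x)
    mu_field[, , , 2] <- vol_of(nfit$mu_y)
    mu_field[, , , 3] <- vol_of(nfit$mu_z)
    cs <- if (st$cosine) similarity_volumes(mu_field, axes) else
      stop("stage 'cosine' cannot be disabled while sampling runs")

    # synthetic T1w/T2w volume: myelin proxy tracking neurite density
    old <- .Random.seed_save()
    set.seed(.stage_seed(config, "t1wt2w", s))
    t1_noise <- stats::rnorm(length(lin), 0, 0.05)
    .Random.seed_restore(old)
    vols <- list(odi = vol_of(nfit$odi), ndi = vol_of(nfit$f_ic),
                 fa = vol_of(dfit$FA), md = vol_of(dfit$MD),
                 t1wt2w = vol_of(1.1 + 0.8 * truth$f_ic[lin] + t1_noise),
                 cs_AP = cs$cs_AP, cs_PD = cs$cs_PD, cs_IO = cs$cs_IO)
    subj_maps[[sid]] <- stats::setNames(lapply(metrics_vol, function(m) {
      mp <- sample_to_midthickness(vols[[m]], surface, domain$voxel_size_mm,
                                   metric = m, subject = sid, hemisphere = "L")
      write_unfolded_csv(mp, file.path(out, sprintf("map_%s_%s.csv", sid, m)))
      mp
    }), metrics_vol)
  }
  timings["subjects"] <- tic() - t0

  # ---- averaging ----------------------------------------------------------
  t0 <- tic()
  mean_maps <- stats::setNames(lapply(metrics_vol, function(m) {
    avg <- average_maps(lapply(subj_maps, `[[`, m))
    write_unfolded_csv(avg$mean, file.path(out, sprintf("mean_%s.csv", m)))
    avg$mean
  }), metrics_vol)
  timings["average"] <- tic() - t0

  # ---- correlations + spin test -------------------------------------------
  t0 <- tic()
  report <- all_pairs_report(mean_maps, n_perm = config$n_perm,
                             seed = .stage_seed(config, "spin"),
                             spin = isTRUE(st$spin))
  write_correlation_csv(report, file.path(out, "correlations"))
  timings["spin"] <- tic() - t0

  # ---- subfield separability ----------------------------------------------
  t0 <- tic()
  class_report <- NULL
  if (st$classify) {
    tab <- do.call(rbind, lapply(subj_ids, function(sid) {
      rows <- lapply(c("odi", "ndi", "t1wt2w"), function(m) {
        subfield_average(subj_maps[[sid]][[m]], surface$subfield)
      })
      data.frame(subject = sid, hemisphere = "L",
                 subfield = factor(SUBFIELDS, levels = SUBFIELDS),
                 odi = rows[[1]], ndi = rows[[2]], t1wt2w = rows[[3]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, file.path(out, "subfield_table.csv"), row.names = FALSE)
    class_report <- subfield_separability(tab, seed = .stage_seed(config, "classify"))
    utils::write.csv(class_report$metrics, file.path(out, "classifier_f1.csv"),
                     row.names = FALSE)
  }
  timings["classify"] <- tic() - t0

  # ---- OPNNMF -------------------------------------------------------------
  t0 <- tic()
  opnnmf_res <- NULL; stability <- NULL
  if (st$opnnmf) {
    V <- prod(config$grid_shape)
    cols <- expand.grid(metric = metrics_vol, subject = subj_ids,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    Xraw <- vapply(seq_len(nrow(cols)), function(i) {
      v <- subj_maps[[cols$subject[i]]][[cols$metric[i]]]$values
      v[!is.finite(v)] <- mean(v, na.rm = TRUE)
      v
    }, numeric(V))
    stack <- normalize_metrics(Xraw, columns = cols, hemisphere = "L")
    opnnmf_res <- opnnmf_fit(stack, config$k_parcel, max_iter = 2000L)
    utils::write.csv(data.frame(vertex = seq_len(V), label = opnnmf_res$labels),
                     file.path(out, "opnnmf_labels.csv"), row.names = FALSE)
    utils::write.csv(opnnmf_res$C, file.path(out, "opnnmf_C.csv"), row.names = FALSE)
    utils::write.csv(zscore_weights(opnnmf_res$W), file.path(out, "opnnmf_Wz.csv"),
                     row.names = FALSE)
    stability <- stability_analysis(stack, k_range = config$k_range,
                                    n_splits = config$n_splits,
                                    seed = .stage_seed(config, "opnnmf"),
                                    max_iter = 2000L)
    utils::write.csv(as.data.frame(stability), file.path(out, "stability.csv"),
                     row.names = FALSE)
  }
  timings["opnnmf"] <- tic() - t0

  # ---- manifest -----------------------------------------------------------
  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out, files))
  names(hashes) <- files
  manifest <- list(
    package = "hippmap",
    version = as.character(utils::packageVersion("hippmap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config)[setdiff(names(config), "stages")],
    stages_run = st,
    seeds = list(root = config$seed,
                 spin = .stage_seed(config, "spin"),
                 classify = .stage_seed(config, "classify"),
                 opnnmf = .stage_seed(config, "opnnmf")),
    timings_sec = as.list(round(timings, 2)),
    files = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(mean_maps = mean_maps, correlation = report,
                 classifier = class_report, opnnmf = opnnmf_res,
                 stability = stability, manifest = manifest,
                 out_dir = out))
}

# Flat midthickness surface centred in the slab's physical extent.
.pipeline_surface <- function(domain, grid_shape) {
  ext <- dim(domain$mask) * domain$voxel_size_mm
  margin <- 1
  sp <- c((ext[1] - 2 * margin) / max(grid_shape[1] - 1, 1),
          (ext[2] - 2 * margin) / max(grid_shape[2] - 1, 1))
  make_flat_surface(grid_shape, spacing_mm = sp,
                    origin_mm = c(margin, margin, ext[3] / 2),
                    thickness_mm = min(ext[3] - 2, 2))
}
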