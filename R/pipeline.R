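# End-to-end orchestration: simulate -> reconstruct -> unmix/ROI,
# histo-sim -> segment -> TVP, cohort -> tests, with a JSON run manifest.

PIPELINE_STAGES <- c("simulate", "reconstruct", "oximetry", "histology", "cohort")

#' Load and validate a run configuration
#'
#' Accepts an R list, or a path to a YAML or JSON file. Minimal schema: a
#' `stages` character vector (subset of simulate, reconstruct, oximetry,
#' histology, cohort, in dependency order), `seed`, `out_dir`, and one config
#' block per requested stage (reconstruct and oximetry require simulate's
#' block for the phantom and illumination definitions).
#'
#' @param config list or file path.
#' @return validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$stages)) config$stages <- character()
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage(s): %s (known: %s)", paste(bad, collapse = ", "),
                 paste(PIPELINE_STAGES, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set `out_dir`", call. = FALSE)
  needs_sim <- intersect(c("simulate", "reconstruct", "oximetry"), config$stages)
  if (length(needs_sim) > 0 && is.null(config$simulate)) {
    stop("stages simulate/reconstruct/oximetry require a `simulate` config block",
         call. = FALSE)
  }
  for (st in intersect(config$stages, c("histology", "cohort"))) {
    if (is.null(config[[st]])) {
      stop(sprintf("stage '%s' requires a `%s` config block", st, st), call. = FALSE)
    }
  }
  config
}

# per-stage seed fan-out: global_seed * 100 + fixed stage ordinal, so stages
# are independently reproducible under one global seed
stage_seed <- function(global_seed, stage) {
  as.integer(global_seed) * 100L + match(stage, PIPELINE_STAGES)
}

parse_structures <- function(lst) {
  lapply(lst, function(s) {
    switch(s$kind,
      lesion_sphere = lesion_sphere(s$center_mm, s$radius_mm,
                                    s$total_hemoglobin, s$so2_true,
                                    id = if (is.null(s$id)) "lesion" else s$id),
      vessel_tube = vessel_tube(s$center_mm, s$axis_mm, s$radius_mm,
                                s$half_length_mm, s$total_hemoglobin, s$so2_true,
                                id = if (is.null(s$id)) "vessel" else s$id),
      subcutaneous_vessel = subcutaneous_vessel(s$center_mm, s$axis_mm,
                                                s$radius_mm, s$half_length_mm,
                                                s$total_hemoglobin, s$so2_true,
                                                id = if (is.null(s$id)) "subcutaneous" else s$id),
      stop(sprintf("unknown structure kind '%s'", s$kind), call. = FALSE))
  })
}

config_eps <- function(cfg) {
  if (is.null(cfg)) default_extinction()
  else extinction_table(cfg$wavelengths_nm, cfg$eps_hbo2, cfg$eps_hb)
}

#' Run the pipeline described by a configuration
#'
#' Executes the requested stages in dependency order, writes every artifact
#' under `out_dir`, and returns (and writes) a run manifest listing the seed,
#' a reorder-stable config hash, and each stage's inputs, outputs and status.
#' Rerunning with an identical config and seed reproduces all numeric outputs
#' bit for bit. A failing stage is recorded in the manifest with its error
#' and the remaining stages are not run.
#'
#' @param config list or YAML/JSON path (see [load_run_config()]).
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "pamoxi",
                   version = as.character(utils::packageVersion("pamoxi")),
                   seed = cfg$seed,
                   config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
                   out_dir = cfg$out_dir,
                   stages = list())
  state <- new.env(parent = emptyenv())
  for (st in cfg$stages) {
    rec <- list(stage = st, seed = stage_seed(cfg$seed, st), outputs = character())
    res <- tryCatch({
      rec$outputs <- run_stage(st, cfg, state, rec$seed)
      rec$status <- "ok"
      rec
    }, error = function(e) {
      rec$status <- "failed"
      rec$error <- conditionMessage(e)
      rec
    })
    manifest$stages[[st]] <- res
    if (res$status == "failed") break
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

run_stage <- function(st, cfg, state, seed) {
  out <- cfg$out_dir
  switch(st,
    simulate = {
      sc <- cfg$simulate
      ph_cfg <- sc$phantom
      spec <- phantom_spec(unlist(ph_cfg$grid_shape), ph_cfg$voxel_pitch_mm,
                           background_mua = unlist(ph_cfg$background_mua),
                           background_musp = ph_cfg$background_musp %||% 10,
                           grueneisen = ph_cfg$grueneisen %||% 0.20,
                           breast_thickness_mm = ph_cfg$breast_thickness_mm,
                           structures = parse_structures(ph_cfg$structures))
      state$phantom <- build_breast_phantom(spec, seed = seed)
      state$illum <- do.call(illumination_config, sc$illumination %||% list())
      state$array <- do.call(detector_array, sc$array %||% list())
      state$eps <- config_eps(cfg$oximetry$eps)
      files <- character()
      state$sinograms <- list()
      for (wl in state$illum$wavelengths_nm) {
        phi <- fluence_map(state$phantom, state$illum, wl)
        p0 <- initial_pressure_map(state$phantom, phi, wl, state$eps)
        sg <- simulate_sinogram(p0, state$array, seed = seed,
                                noise_sd = sc$noise_sd %||% 0,
                                bandlimit = isTRUE(sc$bandlimit))
        pre <- file.path(out, sprintf("sinogram_%d", wl))
        files <- c(files, write_sinogram(sg, pre))
        state$sinograms[[as.character(wl)]] <- sg
      }
      files
    },
    reconstruct = {
      if (is.null(state$sinograms)) stop("reconstruct requires the simulate stage", call. = FALSE)
      rc <- cfg$reconstruct %||% list()
      grid <- if (!is.null(rc$voxel_pitch_mm) || !is.null(rc$extent_mm)) {
        recon_grid(unlist(rc$extent_mm) %||%
                     (state$phantom$grid_shape * state$phantom$voxel_pitch_mm),
                   rc$voxel_pitch_mm %||% 0.25)
      } else {
        recon_grid(state$phantom$grid_shape * state$phantom$voxel_pitch_mm,
                   state$phantom$voxel_pitch_mm)
      }
      files <- character()
      state$volumes <- list()
      for (wl in names(state$sinograms)) {
        vol <- ubp_reconstruct(state$sinograms[[wl]], grid)
        pre <- file.path(out, sprintf("recon_%s", wl))
        files <- c(files, write_pam_volume(vol, pre))
        state$volumes[[wl]] <- vol
      }
      mip <- mip_slabs(state$volumes[[2]], rc$mip_slab_mm %||% 2, axis = 3)
      state$mip <- mip
      mip_csv <- file.path(out, "mip_slab1.csv")
      utils::write.csv(mip$slabs[[1]], mip_csv, row.names = FALSE)
      c(files, mip_csv)
    },
    oximetry = {
      if (is.null(state$volumes)) stop("oximetry requires the reconstruct stage", call. = FALSE)
      oc <- cfg$oximetry %||% list()
      wls <- state$illum$wavelengths_nm
      mua <- list()
      for (i in 1:2) {
        vol <- state$volumes[[as.character(wls[i])]]
        phi_src <- fluence_map(state$phantom, state$illum, wls[i])
        # fluence resampled onto the reconstruction grid (nearest voxel in z)
        phi <- resample_volume(phi_src, vol)
        mua[[i]] <- estimate_absorption(vol, phi, state$phantom$grueneisen)
      }
      un <- unmix_chromophores(mua[[1]], mua[[2]], state$eps)
      so2 <- so2_from_concentrations(un$c_hbo, un$c_hb, oc$thc_floor)
      state$so2 <- so2
      files <- write_pam_volume(so2$so2, file.path(out, "so2"))
      rois <- lapply(oc$rois %||% list(), function(r) do.call(roi_spec, r))
      if (length(rois) > 0) {
        summaries <- lapply(rois, function(r) roi_statistics(so2, r))
        df <- do.call(rbind, lapply(summaries, function(s)
          data.frame(kind = s$kind, n_voxels = s$n_voxels, n_valid = s$n_valid,
                     median = s$median, mean = s$mean, q1 = s$q1, q3 = s$q3,
                     n_flagged = s$n_flagged, empty = s$empty)))
        roi_csv <- file.path(out, "roi_summary.csv")
        utils::write.csv(df, roi_csv, row.names = FALSE)
        files <- c(files, roi_csv)
        state$roi_summaries <- summaries
      }
      files
    },
    histology = {
      hc <- cfg$histology
      spec_args <- hc[intersect(names(hc),
        c("tile_px", "pixel_pitch_um", "vessels", "n_vessels", "radius_range_px",
          "lumen_prob", "lesion", "stain_rgb", "background_rgb"))]
      hspec <- do.call(histology_spec, spec_args)
      hp <- generate_histology(hspec, seed = seed)
      mask <- hsi_segment(hp$rgb, hp$stain_window)
      vm <- object_perimeters(mask, hp$pixel_pitch_um)
      bm <- tvp_block_map(vm, block_size_mm = hc$block_size_mm %||% 0.84)
      files <- character()
      truth_csv <- file.path(out, "vessel_truth.csv")
      utils::write.csv(hp$vessel_truth, truth_csv, row.names = FALSE)
      per_csv <- file.path(out, "vessel_perimeters.csv")
      utils::write.csv(vm$perimeters, per_csv, row.names = FALSE)
      bm_csv <- file.path(out, "tvp_blockmap.csv")
      utils::write.csv(bm$tvp_um, bm_csv, row.names = FALSE)
      files <- c(files, truth_csv, per_csv, bm_csv)
      if (!is.null(hp$lesion_mask)) {
        sel <- select_lesion_blocks(bm, hp$lesion_mask, hc$min_overlap %||% 0.5)
        res <- lesional_tvp_per_area(bm, sel)
        les_csv <- file.path(out, "lesional_tvp.csv")
        utils::write.csv(data.frame(n_blocks = nrow(res$selection),
                                    tvp_um = res$tvp_um, area_mm2 = res$area_mm2,
                                    ratio_um_per_mm2 = res$ratio_um_per_mm2),
                         les_csv, row.names = FALSE)
        files <- c(files, les_csv)
        state$lesion_tvp <- res
      }
      state$blockmap <- bm
      files
    },
    cohort = {
      cc <- cfg$cohort
      cspec <- do.call(cohort_spec, cc[intersect(names(cc), names(formals(cohort_spec)))])
      tab <- cohort_sampler(cspec, seed = seed)
      files <- file.path(out, "cohort.csv")
      utils::write.csv(tab, files, row.names = FALSE)
      vis <- visibility_summary(tab)
      w_sub <- wilcoxon_signed_rank(tab$so2_lesion, tab$so2_subcutaneous)
      w_con <- wilcoxon_signed_rank(tab$so2_lesion, tab$so2_contralateral)
      mal <- tab[tab$class != "benign", ]
      mw <- if (length(unique(mal$caix)) == 2)
        mann_whitney_u(mal$tvp_area[mal$caix], mal$tvp_area[!mal$caix]) else NULL
      tests <- data.frame(
        test = c("wilcoxon_lesion_vs_subcutaneous", "wilcoxon_lesion_vs_contralateral",
                 if (!is.null(mw)) "mann_whitney_tvp_by_caix"),
        statistic = c(w_sub$statistic, w_con$statistic, if (!is.null(mw)) mw$statistic),
        p_value = c(w_sub$p_value, w_con$p_value, if (!is.null(mw)) mw$p_value))
      tests_csv <- file.path(out, "cohort_tests.csv")
      utils::write.csv(tests, tests_csv, row.names = FALSE)
      vis_json <- file.path(out, "visibility.json")
      jsonlite::write_json(vis, vis_json, auto_unbox = TRUE, digits = NA)
      state$cohort <- tab
      c(files, tests_csv, vis_json)
    },
    stop(sprintf("unknown stage '%s'", st), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest-voxel resample of `src` onto the grid of `template`
resample_volume <- function(src, template) {
  if (identical(dim(src$data), dim(template$data)) &&
      isTRUE(all.equal(src$pitch_mm, template$pitch_mm))) {
    return(src)
  }
  n <- dim(template$data)
  idx <- lapply(1:3, function(ax) {
    ctr <- template$origin[ax] + (seq_len(n[ax]) - 0.5) * template$pitch_mm
    i <- round((ctr - src$origin[ax]) / src$pitch_mm + 0.5)
    pmin(pmax(i, 1L), dim(src$data)[ax])
  })
  pam_volume(src$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
             template$pitch_mm, template$origin,
             wavelength_nm = src$wavelength_nm, units = src$units, kind = src$kind)
}

#' Demonstration run configuration
#'
#' A compact full-pipeline configuration: a two-structure breast phantom
#' (hypoxic lesion sphere at depth, high-SO2 subcutaneous vessel, plus a
#' contralateral-normal vessel at the lesion depth), dual 756/797 nm
#' illumination, the 15 x 23 array, reconstruction at the phantom pitch, ROI
#' summaries, a synthetic CD31 tile with a lesion mask, and the default
#' 39-lesion cohort. Grid sizes are kept modest (40^3 voxels at 0.5 mm) so a
#' demo runs in seconds to minutes.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return a config list for [run_pipeline()].
#' @export
demo_run_config <- function(out_dir, seed = 1L) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "reconstruct", "oximetry", "histology", "cohort"),
    simulate = list(
      phantom = list(
        grid_shape = c(40, 40, 40), voxel_pitch_mm = 0.5,
        background_mua = c("756" = 0, "797" = 0), background_musp = 10,
        grueneisen = 0.20,
        structures = list(
          list(kind = "lesion_sphere", id = "lesion", center_mm = c(10, 10, 12),
               radius_mm = 2.5, total_hemoglobin = 1e-4, so2_true = 0.60),
          list(kind = "subcutaneous_vessel", id = "subcut", center_mm = c(10, 10, 4),
               axis_mm = c(0, 1, 0), radius_mm = 1.2, half_length_mm = 6,
               total_hemoglobin = 1e-4, so2_true = 0.85),
          list(kind = "vessel_tube", id = "contralateral", center_mm = c(14, 10, 12),
               axis_mm = c(0, 1, 0), radius_mm = 1.2, half_length_mm = 6,
               total_hemoglobin = 1e-4, so2_true = 0.80))),
      illumination = list(wavelengths_nm = c(756, 797), surface_fluence = 1),
      array = list(center_mm = c(10, 10)),
      noise_sd = 0),
    reconstruct = list(mip_slab_mm = 2),
    oximetry = list(rois = list(
      list(kind = "lesion", shape = "sphere", center_mm = c(10, 10, 12), radius_mm = 2),
      list(kind = "subcutaneous_vessel", shape = "sphere", center_mm = c(10, 10, 4), radius_mm = 1.2),
      list(kind = "contralateral_normal", shape = "sphere", center_mm = c(14, 10, 12), radius_mm = 1.2))),
    histology = list(tile_px = 2000, pixel_pitch_um = 0.42, n_vessels = 12,
                     radius_range_px = c(25, 60), lumen_prob = 0.5,
                     lesion = list(center_px = c(1000, 1000), radius_px = 900),
                     block_size_mm = 0.84, min_overlap = 0.5),
    cohort = list()
  )
}

#' Render a run report from a manifest
#'
#' Produces `report.md` in the run directory with the ROI/cohort SO2 summary,
#' a TVP block heat map (PNG via ggplot2), a cohort SO2 box plot, and the
#' cohort test table. Artifacts missing from the manifest are listed as
#' absent; the report is still produced. Regeneration from the same manifest
#' is byte-identical (no timestamps are embedded).
#'
#' @param manifest a manifest list from [run_pipeline()] or a path to
#'   `manifest.json`.
#' @return path to `report.md`, invisibly.
#' @export
make_report <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  out <- manifest$out_dir
  lines <- c("# PAM pipeline run report", "",
             sprintf("- package: pamoxi %s", manifest$version),
             sprintf("- seed: %s", manifest$seed),
             sprintf("- config hash: %s", manifest$config_hash), "")
  have <- function(f) file.exists(file.path(out, f))
  missing <- character()

  lines <- c(lines, "## ROI oxygen saturation", "")
  if (have("roi_summary.csv")) {
    roi <- utils::read.csv(file.path(out, "roi_summary.csv"))
    lines <- c(lines, df_to_md(roi), "")
  } else {
    missing <- c(missing, "roi_summary.csv")
    lines <- c(lines, "_ROI summary absent._", "")
  }

  lines <- c(lines, "## Cohort SO2 distributions", "")
  if (have("cohort.csv")) {
    tab <- utils::read.csv(file.path(out, "cohort.csv"))
    long <- data.frame(
      roi = rep(c("lesion", "subcutaneous", "contralateral"), each = nrow(tab)),
      so2 = c(tab$so2_lesion, tab$so2_subcutaneous, tab$so2_contralateral))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = roi, y = so2)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "SO2 (fraction)", x = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out, "so2_boxplot.png"), p,
                    width = 5, height = 4, dpi = 120)
    lines <- c(lines, "![SO2 box plot](so2_boxplot.png)", "")
  } else {
    missing <- c(missing, "cohort.csv")
    lines <- c(lines, "_Cohort table absent._", "")
  }

  lines <- c(lines, "## TVP block heat map", "")
  if (have("tvp_blockmap.csv")) {
    bm <- as.matrix(utils::read.csv(file.path(out, "tvp_blockmap.csv")))
    df <- expand.grid(row = seq_len(nrow(bm)), col = seq_len(ncol(bm)))
    df$tvp <- as.vector(bm)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = tvp)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(fill = "TVP (um)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out, "tvp_heatmap.png"), p,
                    width = 5, height = 4, dpi = 120)
    lines <- c(lines, "![TVP heat map](tvp_heatmap.png)", "")
  } else {
    missing <- c(missing, "tvp_blockmap.csv")
    lines <- c(lines, "_TVP block map absent._", "")
  }

  lines <- c(lines, "## Cohort tests", "")
  if (have("cohort_tests.csv")) {
    lines <- c(lines, df_to_md(utils::read.csv(file.path(out, "cohort_tests.csv"))), "")
  } else {
    missing <- c(missing, "cohort_tests.csv")
    lines <- c(lines, "_Cohort tests absent._", "")
  }

  if (length(missing) > 0) {
    lines <- c(lines, "## Missing artifacts", "", paste("-", missing), "")
  }
  path <- file.path(out, "report.md")
  writeLines(lines, path)
  invisible(path)
}

df_to_md <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "g", digits = 6) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
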