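# Pipeline orchestration: ties photo-stack assembly, the cross-modality
# similarity + B-spline registration steps, WSS projection, QC and the
# relocation sensitivity analysis into one reproducible run, with on-disk
# specimen bundles, a manifest, and structured per-stage outputs.

#' Merge contour stacks
#' @param ... [contour_stack()]s with disjoint (slice, structure) keys.
#' @return combined [contour_stack()].
#' @export
merge_contour_stacks <- function(...) {
  stacks <- list(...)
  entries <- do.call(c, lapply(stacks, `[[`, "entries"))
  seen <- character()
  keep <- logical(length(entries))
  for (i in seq_along(entries)) {
    key <- paste(entries[[i]]$slice_index, entries[[i]]$structure)
    keep[i] <- !key %in% seen
    seen <- c(seen, key)
  }
  contour_stack(entries[keep], check_simple = FALSE)
}

#' Write a phantom bundle as an on-disk specimen directory
#'
#' Layout: `photos/sec_###.png`, `landmarks_<modality>.csv`,
#' `contours_<modality>.csv`, `wss_surface.vtp` (in vivo domain),
#' `truth_transforms.json`, `truth_bins.csv`, `meta.json`.
#' @param bundle a `phantom_bundle` from [generate_phantom()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dir <- function(bundle, dir) {
  dir.create(file.path(dir, "photos"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$enface_photos))
    write_photo(bundle$enface_photos[[i]],
                file.path(dir, "photos", sprintf("sec_%03d.png", i - 1L)))
  for (m in names(bundle$landmarks))
    write_landmarks(bundle$landmarks[[m]],
                    file.path(dir, sprintf("landmarks_%s.csv", m)))
  enface_all <- merge_contour_stacks(bundle$enface_contours,
                                     bundle$enface_wall_contours)
  write_contours(enface_all, file.path(dir, "contours_enface.csv"))
  write_contours(bundle$histology_contours, file.path(dir, "contours_histology.csv"))
  write_contours(bundle$invivo_contours, file.path(dir, "contours_invivo.csv"))
  write_contours(bundle$exvivo_contours, file.path(dir, "contours_exvivo.csv"))
  write_surface(bundle$wss_surface, file.path(dir, "wss_surface.vtp"))
  write_transforms(bundle$truth_transforms, file.path(dir, "truth_transforms.json"))
  .write_csv(bundle$truth_bin_values, file.path(dir, "truth_bins.csv"))
  lm <- bundle$enface_photos[[1]]
  meta <- list(n_sections = bundle$spec$n_sections,
               section_spacing_mm = bundle$spec$section_spacing_mm,
               reference_slice_index = bundle$spec$reference_slice_index,
               pixel_size_mm = lm$pixel_size_mm,
               section_z_mm = bundle$section_z_mm,
               rng_seed = bundle$spec$rng_seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a specimen directory written by [write_phantom_dir()]
#' @param dir specimen directory.
#' @param specimen_id id used in downstream tables (default: directory name).
#' @return specimen input list for [run_specimen_pipeline()].
#' @export
read_phantom_dir <- function(dir, specimen_id = basename(dir)) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  photo_files <- sort(list.files(file.path(dir, "photos"), pattern = "\\.png$",
                                 full.names = TRUE))
  lm_hist <- read_landmarks(file.path(dir, "landmarks_histology.csv"))
  lm_enf <- read_landmarks(file.path(dir, "landmarks_enface.csv"))
  photos <- lapply(seq_along(photo_files), function(i) {
    # en-face photo landmarks: for this bundle layout the stacking landmarks
    # equal the en-face frame landmarks on every slice (labels are shared)
    read_photo(photo_files[i], meta$pixel_size_mm, meta$section_z_mm[i],
               lm_enf[, c("label", "x_mm", "y_mm")])
  })
  list(specimen_id = specimen_id,
       meta = meta,
       photos = photos,
       landmarks = list(enface = lm_enf,
                        exvivo = read_landmarks(file.path(dir, "landmarks_exvivo.csv")),
                        invivo = read_landmarks(file.path(dir, "landmarks_invivo.csv")),
                        histology = lm_hist),
       enface_contours = read_contours(file.path(dir, "contours_enface.csv")),
       histology_contours = read_contours(file.path(dir, "contours_histology.csv")),
       invivo_contours = read_contours(file.path(dir, "contours_invivo.csv")),
       exvivo_contours = read_contours(file.path(dir, "contours_exvivo.csv")),
       wss_surface = read_surface(file.path(dir, "wss_surface.vtp")))
}

#' Specimen input from an in-memory phantom bundle
#' @param bundle a `phantom_bundle`.
#' @param specimen_id id used in downstream tables.
#' @return specimen input list for [run_specimen_pipeline()].
#' @export
specimen_from_bundle <- function(bundle, specimen_id = "phantom") {
  list(specimen_id = specimen_id,
       meta = list(n_sections = bundle$spec$n_sections,
                   section_spacing_mm = bundle$spec$section_spacing_mm,
                   reference_slice_index = bundle$spec$reference_slice_index,
                   section_z_mm = bundle$section_z_mm),
       photos = bundle$enface_photos,
       landmarks = bundle$landmarks,
       enface_contours = merge_contour_stacks(bundle$enface_contours,
                                              bundle$enface_wall_contours),
       histology_contours = bundle$histology_contours,
       invivo_contours = bundle$invivo_contours,
       exvivo_contours = bundle$exvivo_contours,
       wss_surface = bundle$wss_surface)
}

.lm_points <- function(df, slice) {
  g <- df[df$slice_index == slice, ]
  g <- g[order(g$label), ]
  list(labels = g$label, pts = cbind(g$x_mm, g$y_mm))
}

#' Run registration, projection and QC for one specimen
#'
#' Implements the registration chain: en-face stack assembly (landmark rigid
#' fits), step A (in vivo -> ex vivo: reference-slice similarity + per-slice
#' contour B-spline), step B (ex vivo -> en-face: same recipe), step C
#' (histology -> en-face: per-slice similarity), then maps the WSS surface
#' through the composed chain, computes the centerline, radial bin statistics,
#' plaque thickness and per-section DSC/HD metrics.
#'
#' @param specimen input list (see [specimen_from_bundle()] /
#'   [read_phantom_dir()]).
#' @param params a [projection_params()].
#' @param reg_params see [bspline_params()].
#' @param smoothing_window centerline smoothing window (odd; default 3).
#' @return list with the fitted transforms, transformed stacks, centerline,
#'   `sections` (projection inputs), the baseline [bin_table()] and
#'   `section_metrics` (per-section DSC/HD for error types 2 and 3).
#' @export
run_specimen_pipeline <- function(specimen, params = projection_params(),
                                  reg_params = bspline_params(),
                                  smoothing_window = 3) {
  ref <- specimen$meta$reference_slice_index
  stack_res <- stack_enface_photos(specimen$photos)

  # step A: in vivo -> ex vivo
  lm_ex <- .lm_points(specimen$landmarks$exvivo, ref)
  lm_iv <- .lm_points(specimen$landmarks$invivo, ref)
  shared <- intersect(lm_ex$labels, lm_iv$labels)
  sim_A <- fit_similarity_from_landmarks(
    lm_ex$pts[match(shared, lm_ex$labels), , drop = FALSE],
    lm_iv$pts[match(shared, lm_iv$labels), , drop = FALSE])
  invivo_rigid <- transform_contours(specimen$invivo_contours, sim_A)
  bspl_A <- register_contours_bspline(specimen$exvivo_contours, invivo_rigid,
                                      reg_params)

  # step B: ex vivo -> en-face
  lm_enf <- .lm_points(specimen$landmarks$enface, ref)
  shared <- intersect(lm_enf$labels, lm_ex$labels)
  sim_B <- fit_similarity_from_landmarks(
    lm_enf$pts[match(shared, lm_enf$labels), , drop = FALSE],
    lm_ex$pts[match(shared, lm_ex$labels), , drop = FALSE])
  exvivo_rigid <- transform_contours(specimen$exvivo_contours, sim_B)
  bspl_B <- register_contours_bspline(specimen$enface_contours, exvivo_rigid,
                                      reg_params)

  # step C: histology -> en-face, per-slice similarity
  hist_slices <- stack_slices(specimen$histology_contours)
  sims_C <- stats::setNames(lapply(hist_slices, function(s) {
    lm_h <- .lm_points(specimen$landmarks$histology, s)
    lm_e <- .lm_points(specimen$landmarks$enface, ref)
    shared <- intersect(lm_e$labels, lm_h$labels)
    fit_similarity_from_landmarks(
      lm_e$pts[match(shared, lm_e$labels), , drop = FALSE],
      lm_h$pts[match(shared, lm_h$labels), , drop = FALSE])
  }), as.character(hist_slices))

  # composed chain applied to the in vivo contours and the WSS surface
  section_z <- stats::setNames(
    vapply(hist_slices, function(s) stack_z(specimen$histology_contours, s),
           numeric(1)), as.character(hist_slices))
  invivo_enface <- transform_contours(invivo_rigid, .slicewise_for(bspl_A, invivo_rigid))
  invivo_enface <- transform_contours(invivo_enface, sim_B)
  invivo_enface <- transform_contours(invivo_enface, .slicewise_for(bspl_B, invivo_enface))
  hist_enface <- transform_contours(specimen$histology_contours, sims_C)

  wss_enface <- transform_surface(specimen$wss_surface, sim_A)
  wss_enface <- transform_surface(wss_enface, bspl_A, section_z)
  wss_enface <- transform_surface(wss_enface, sim_B)
  wss_enface <- transform_surface(wss_enface, bspl_B, section_z)

  centerline <- compute_centerline(.lumen_only(invivo_enface), smoothing_window)

  sections <- lapply(hist_slices, function(s) {
    cp <- unlist(centerline[centerline$slice_index == s, c("x_mm", "y_mm")])
    th <- NULL
    lum <- stack_get(hist_enface, s, "lumen")
    med <- stack_get(hist_enface, s, "media")
    if (!is.null(lum) && !is.null(med))
      th <- plaque_thickness_per_bin(lum, med, cp, params)
    list(specimen_id = specimen$specimen_id, slice_index = s,
         z_mm = section_z[[as.character(s)]], centerpoint = cp, thickness = th)
  })
  processed <- lapply(sections, function(s) {
    s$wss <- project_wss_to_section(wss_enface, s$z_mm, s$centerpoint, params)
    s
  })
  baseline_table <- build_bin_table(processed)

  section_metrics <- do.call(rbind, lapply(hist_slices, function(s) {
    enf <- stack_get(specimen$enface_contours, s, "lumen")
    h <- stack_get(hist_enface, s, "lumen")
    iv <- stack_get(invivo_enface, s, "lumen")
    data.frame(specimen_id = specimen$specimen_id, slice_index = s,
               dsc_type2 = dice_from_contours(enf, h),
               hd_type2_mm = hausdorff_distance(enf, h, 0.05),
               dsc_type3 = dice_from_contours(enf, iv),
               hd_type3_mm = hausdorff_distance(enf, iv, 0.05))
  }))

  list(photo_stack = stack_res,
       transforms = list(sim_A = sim_A, bspl_A = bspl_A, sim_B = sim_B,
                         bspl_B = bspl_B, sims_C = sims_C),
       invivo_enface = invivo_enface, hist_enface = hist_enface,
       wss_enface = wss_enface, centerline = centerline,
       sections = sections, baseline_table = baseline_table,
       section_metrics = section_metrics)
}

# restrict a per-slice transform list to the slices present in a stack
.slicewise_for <- function(tfs, stack) {
  keys <- as.character(stack_slices(stack))
  missing <- setdiff(keys, names(tfs))
  if (length(missing)) stop("no transform for slice(s) ", paste(missing, collapse = ", "))
  tfs[keys]
}

.lumen_only <- function(stack)
  contour_stack(Filter(function(e) e$structure == "lumen", stack$entries),
                check_simple = FALSE)

#' Pipeline configuration
#'
#' @param specimens list of specimen sources: either paths to specimen
#'   directories (character) or in-memory specimen lists.
#' @param output_dir where outputs are written.
#' @param params a [projection_params()].
#' @param reg_params see [bspline_params()].
#' @param relocations_mm relocation sweep (must contain 0).
#' @param flags data.frame of error flags (or path to a flags CSV), optional.
#' @param seed integer master seed (recorded in the manifest; drives the
#'   registration sampling via `reg_params$seed` when that is NULL).
#' @param write_overlays write per-section QC overlay PNGs.
#' @return validated config list.
#' @export
pipeline_config <- function(specimens, output_dir,
                            params = projection_params(),
                            reg_params = bspline_params(),
                            relocations_mm = c(-0.6, -0.3, 0, 0.3, 0.6),
                            flags = NULL, seed = 1L, write_overlays = FALSE) {
  if (!length(specimens)) stop("config needs at least one specimen")
  for (sp in specimens)
    if (is.character(sp) && !dir.exists(sp))
      stop("specimen directory does not exist: ", sp)
  if (is.character(flags) && !file.exists(flags))
    stop("flags CSV does not exist: ", flags)
  if (!0 %in% relocations_mm) relocations_mm <- sort(c(0, relocations_mm))
  list(specimens = specimens, output_dir = output_dir, params = params,
       reg_params = reg_params, relocations_mm = sort(relocations_mm),
       flags = flags, seed = as.integer(seed), write_overlays = write_overlays)
}

#' Run the full pipeline
#'
#' Registers every specimen, projects WSS onto radial bins, applies exclusion
#' flags, computes QC summaries, runs the relocation sensitivity sweep and
#' writes all outputs (transforms JSON, bin-table CSV, QC CSVs, sensitivity
#' CSVs, optional overlay PNGs, and a manifest) under `config$output_dir`.
#' Deterministic for a fixed config/seed.
#'
#' @param config from [pipeline_config()].
#' @param stages subset of `c("register", "project", "qc", "sensitivity")`;
#'   later stages imply the earlier ones.
#' @return list with the merged flagged [bin_table()], per-dz tables, QC
#'   summary, sensitivity results and per-specimen pipeline outputs.
#' @export
run_pipeline <- function(config, stages = c("register", "project", "qc",
                                            "sensitivity")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$reg_params$seed)) config$reg_params$seed <- config$seed

  specimens <- lapply(config$specimens, function(sp)
    if (is.character(sp)) read_phantom_dir(sp) else sp)

  runs <- lapply(specimens, function(sp) {
    res <- tryCatch(
      run_specimen_pipeline(sp, config$params, config$reg_params),
      error = function(e) stop("stage 'register/project' failed for specimen '",
                               sp$specimen_id, "': ", conditionMessage(e)))
    write_transforms(transform_chain(list(res$transforms$sim_A, res$transforms$sim_B)),
                     file.path(out_dir, paste0("similarity_chain_",
                                               sp$specimen_id, ".json")))
    write_transforms(res$transforms$bspl_A,
                     file.path(out_dir, paste0("bspline_A_", sp$specimen_id, ".json")))
    write_transforms(res$transforms$bspl_B,
                     file.path(out_dir, paste0("bspline_B_", sp$specimen_id, ".json")))
    write_transforms(res$transforms$sims_C,
                     file.path(out_dir, paste0("histology_sims_", sp$specimen_id, ".json")))
    write_centerline(res$centerline,
                     file.path(out_dir, paste0("centerline_", sp$specimen_id, ".csv")))
    res
  })
  names(runs) <- vapply(specimens, `[[`, character(1), "specimen_id")

  merged <- bin_table(do.call(rbind, lapply(runs, function(r)
    as.data.frame(r$baseline_table))))

  flags <- config$flags
  if (is.character(flags)) flags <- read_error_flags(flags)
  if (is.null(flags))
    flags <- data.frame(specimen_id = character(), slice_index = integer(),
                        bin_index = integer(), error_type = character())
  merged <- apply_exclusions(merged, flags)
  write_bin_table(merged, file.path(out_dir, "bin_table.csv"))

  qc <- NULL
  if (any(c("qc", "sensitivity") %in% stages)) {
    metrics <- do.call(rbind, lapply(runs, `[[`, "section_metrics"))
    qc <- qc_summary(metrics, merged)
    .write_csv(qc$per_specimen, file.path(out_dir, "qc_per_specimen.csv"))
    .write_csv(qc$cross_specimen, file.path(out_dir, "qc_summary.csv"))
    .write_csv(exclusion_tally(merged), file.path(out_dir, "exclusion_tally.csv"))
  }

  sensitivity <- NULL
  if ("sensitivity" %in% stages) {
    dz_tables <- list()
    for (dz in config$relocations_mm) {
      tabs <- lapply(names(runs), function(id)
        as.data.frame(relocate_and_reproject(runs[[id]]$wss_enface,
                                             runs[[id]]$sections,
                                             config$params, dz)))
      tab <- bin_table(do.call(rbind, tabs))
      tab <- apply_exclusions(tab, flags)
      dz_tables[[as.character(dz)]] <- tab
      write_bin_table(tab, file.path(out_dir, sprintf("bin_table_dz_%+.1f.csv", dz)))
    }
    deltas <- lapply(dz_tables, function(tb) delta_wss(dz_tables[["0"]], tb))
    delta_df <- do.call(rbind, lapply(names(deltas), function(dz)
      data.frame(dz_mm = as.numeric(dz), t(deltas[[dz]]$grand))))
    .write_csv(delta_df, file.path(out_dir, "sensitivity_delta_wss.csv"))
    wilcoxon <- do.call(rbind, lapply(setdiff(names(dz_tables), "0"), function(dz) {
      a <- as.data.frame(dz_tables[["0"]]); b <- as.data.frame(dz_tables[[dz]])
      keep <- a$included & !is.na(a$mean_wss_pa) & !is.na(b$mean_wss_pa)
      data.frame(dz_mm = as.numeric(dz),
                 p_mean = wilcoxon_signed_rank(b$mean_wss_pa[keep], a$mean_wss_pa[keep]),
                 p_min = wilcoxon_signed_rank(b$min_wss_pa[keep], a$min_wss_pa[keep]),
                 p_max = wilcoxon_signed_rank(b$max_wss_pa[keep], a$max_wss_pa[keep]))
    }))
    correlations <- lapply(c(mean = "mean", min = "min", max = "max"),
                           function(st) correlation_sweep(dz_tables, st))
    for (st in names(correlations))
      if (!is.null(correlations[[st]]))
        .write_csv(correlations[[st]],
                   file.path(out_dir, sprintf("sensitivity_correlation_%s.csv", st)))
    .write_csv(wilcoxon, file.path(out_dir, "sensitivity_wilcoxon.csv"))
    sensitivity <- list(tables = dz_tables, deltas = deltas, wilcoxon = wilcoxon,
                        correlations = correlations)
    if (isTRUE(config$write_overlays)) .write_sensitivity_figures(sensitivity, out_dir)
  }

  if (isTRUE(config$write_overlays)) .write_overlays(runs, config$params, out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wsshisto")),
    seed = config$seed,
    relocations_mm = config$relocations_mm,
    params = config$params[c("axial_halfwidth_mm", "n_bins", "bin_zero_deg")],
    reg_params = config$reg_params,
    specimens = vapply(specimens, `[[`, character(1), "specimen_id"),
    n_bins_total = nrow(merged))
  manifest$config_hash <- .config_hash(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(bin_table = merged, qc = qc, sensitivity = sensitivity,
                 runs = runs, manifest = manifest))
}

.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Fig-4-style overlays: histology lumen, bin spokes and WSS-coloured vertices
.write_overlays <- function(runs, params, out_dir) {
  if (!capabilities("png")) return(invisible(NULL))
  for (id in names(runs)) {
    r <- runs[[id]]
    for (s in r$sections) {
      f <- file.path(out_dir, sprintf("overlay_%s_sec%02d.png", id, s$slice_index))
      tryCatch({
        grDevices::png(f, width = 600, height = 600, type = "cairo")
        on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
        lum <- stack_get(r$hist_enface, s$slice_index, "lumen")
        sel <- abs(r$wss_enface$vertices[, 3] - s$z_mm) <= params$axial_halfwidth_mm
        v <- r$wss_enface$vertices[sel, , drop = FALSE]
        w <- r$wss_enface$wss_pa[sel]
        pal <- grDevices::hcl.colors(64, "viridis")
        col <- pal[pmax(1, pmin(64, 1 + floor(63 * (w - min(w)) /
                                                max(1e-12, diff(range(w))))))]
        plot(lum[c(seq_len(nrow(lum)), 1), ], type = "l", asp = 1,
             xlab = "x (mm)", ylab = "y (mm)",
             main = sprintf("%s section %d (z = %g mm)", id, s$slice_index, s$z_mm))
        graphics::points(v[, 1], v[, 2], col = col, pch = 16, cex = 0.6)
        spokes <- params$bin_zero_deg * pi / 180 +
          2 * pi * (seq_len(params$n_bins) - 1) / params$n_bins
        rr <- max(dist_to_polygon(s$centerpoint[1], s$centerpoint[2], lum)) + 2
        for (a in spokes)
          graphics::segments(s$centerpoint[1], s$centerpoint[2],
                             s$centerpoint[1] + rr * cos(a),
                             s$centerpoint[2] + rr * sin(a), lty = 3)
      }, error = function(e) NULL)
    }
  }
  invisible(NULL)
}

# Fig-5-style delta boxplots and Fig-6-style correlation scatter
.write_sensitivity_figures <- function(sensitivity, out_dir) {
  if (!capabilities("png")) return(invisible(NULL))
  tryCatch({
    f <- file.path(out_dir, "sensitivity_delta_boxplot.png")
    grDevices::png(f, width = 900, height = 400, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
    dzs <- setdiff(names(sensitivity$deltas), "0")
    per_loc <- lapply(dzs, function(dz) sensitivity$deltas[[dz]]$per_location$dmean_pa)
    graphics::boxplot(per_loc, names = paste0(dzs, " mm"),
                      ylab = "|delta mean WSS| (Pa)", xlab = "relocation")
  }, error = function(e) NULL)
  invisible(NULL)
}
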