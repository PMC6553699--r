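# Registration-mismatch sensitivity: axial relocation of the WSS field
# relative to the histology stack, per-bin delta-WSS, Wilcoxon signed-rank and
# Pearson statistical kernels, and the WSS-thickness correlation sweep.

#' Shift a WSS surface axially
#'
#' Adds `dz_mm` to every vertex z-coordinate; positive dz moves the field
#' cranially. Scalars and in-plane coordinates are untouched.
#' @param field a [surface_field()].
#' @param dz_mm axial offset, mm.
#' @return shifted [surface_field()].
#' @export
relocate_surface <- function(field, dz_mm) {
  v <- field$vertices
  v[, 3] <- v[, 3] + dz_mm
  surface_field(v, field$faces, field$wss_pa)
}

#' Re-project the WSS field after an axial relocation
#'
#' Runs the identical projection pipeline with every field vertex relocated by
#' `dz_mm`; sections, centerpoints and parameters stay fixed (only the axial
#' sampling window shifts relative to the field). Sections whose window falls
#' off the mesh get empty (`NA`) bins and are reported via the
#' `empty_sections` attribute.
#'
#' @param field [surface_field()] in the en-face domain.
#' @param sections list of lists with `specimen_id`, `slice_index`, `z_mm`,
#'   `centerpoint`, and optionally `thickness` (carried through unchanged).
#' @param params a [projection_params()].
#' @param dz_mm relocation offset (default sweep in the paper-matching
#'   analysis: -0.6, -0.3, 0, +0.3, +0.6).
#' @return a [bin_table()].
#' @export
relocate_and_reproject <- function(field, sections, params = projection_params(),
                                   dz_mm = 0) {
  shifted <- relocate_surface(field, dz_mm)
  empty_sections <- integer()
  processed <- lapply(sections, function(s) {
    wss <- tryCatch(
      project_wss_to_section(shifted, s$z_mm, s$centerpoint, params),
      error = function(e) {
        empty_sections <<- c(empty_sections, s$slice_index)
        data.frame(bin_index = seq_len(params$n_bins) - 1L,
                   mean_wss_pa = NA_real_, min_wss_pa = NA_real_,
                   max_wss_pa = NA_real_, n_vertices = 0L, empty = TRUE)
      })
    list(specimen_id = s$specimen_id, slice_index = s$slice_index, z_mm = s$z_mm,
         wss = wss, thickness = s$thickness)
  })
  out <- build_bin_table(processed)
  attr(out, "empty_sections") <- empty_sections
  attr(out, "dz_mm") <- dz_mm
  out
}

#' Per-bin WSS change after relocation
#'
#' Absolute per-bin differences in mean/min/max WSS between a baseline and a
#' relocated bin table, restricted to bins included (and non-empty) in both.
#'
#' @param baseline,relocated [bin_table()]s with matching keys.
#' @return list with `per_bin` (absolute deltas per bin), `per_location`
#'   (averages per specimen x axial location) and `grand` (grand averages of
#'   `|delta mean|`, `|delta min|`, `|delta max|` over all bins).
#' @export
delta_wss <- function(baseline, relocated) {
  a <- as.data.frame(baseline); b <- as.data.frame(relocated)
  key_a <- paste(a$specimen_id, a$slice_index, a$bin_index)
  key_b <- paste(b$specimen_id, b$slice_index, b$bin_index)
  if (!setequal(key_a, key_b)) stop("bin table keys do not match")
  b <- b[match(key_a, key_b), ]
  keep <- a$included & b$included & !is.na(a$mean_wss_pa) & !is.na(b$mean_wss_pa)
  per_bin <- data.frame(specimen_id = a$specimen_id[keep],
                        slice_index = a$slice_index[keep],
                        z_mm = a$z_mm[keep], bin_index = a$bin_index[keep],
                        dmean_pa = abs(b$mean_wss_pa - a$mean_wss_pa)[keep],
                        dmin_pa = abs(b$min_wss_pa - a$min_wss_pa)[keep],
                        dmax_pa = abs(b$max_wss_pa - a$max_wss_pa)[keep])
  per_location <- do.call(rbind, lapply(
    split(per_bin, paste(per_bin$specimen_id, per_bin$slice_index)),
    function(g) data.frame(specimen_id = g$specimen_id[1],
                           slice_index = g$slice_index[1], z_mm = g$z_mm[1],
                           dmean_pa = mean(g$dmean_pa), dmin_pa = mean(g$dmin_pa),
                           dmax_pa = mean(g$dmax_pa))))
  rownames(per_location) <- NULL
  list(per_bin = per_bin, per_location = per_location,
       grand = c(dmean_pa = mean(per_bin$dmean_pa),
                 dmin_pa = mean(per_bin$dmin_pa),
                 dmax_pa = mean(per_bin$dmax_pa)))
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired test on `paired_a - paired_b`. Zero differences are dropped
#' (documented convention); ties receive average ranks. The null distribution
#' of the positive-rank sum is exact for `n <= 25` (computed by convolution
#' over sign assignments, identical to full enumeration) and a normal
#' approximation with continuity and tie correction is used above.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return two-sided p-value. All-zero differences give `p = 1` with a
#'   warning.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    # exact null: distribution of the positive-rank sum over all 2^n equally
    # likely sign assignments, via convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    probs <- c(1, rep(0, total))  # probs[w + 1] = P(2*W == w)
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(total + 1 - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation with t-distribution p-value
#'
#' Sample Pearson r with the two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom; significance is conventionally read at 0.05.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-zero variance.
#' @param which_statistic optional label (`"mean"`, `"min"`, `"max"`) carried
#'   into the result.
#' @return list of class `correlation_result` with `r`, `p_value`, `n`,
#'   `which_statistic`.
#' @export
pearson_correlation <- function(x, y, which_statistic = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs for a defined p-value")
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx <= 0 || sy <= 0) stop("zero variance; Pearson r undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n, which_statistic = which_statistic),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.4g, n = %d%s)\n", x$r, x$p_value, x$n,
              if (is.na(x$which_statistic)) "" else paste0(", ", x$which_statistic)))
  invisible(x)
}

#' WSS-thickness correlation across a relocation sweep
#'
#' For each axial location (specimen x slice) with at least 3 included,
#' non-empty bins carrying thickness, computes the Pearson correlation between
#' the chosen WSS statistic and plaque thickness for every relocation case,
#' plus the change in r relative to the baseline (`dz = 0`) table.
#'
#' @param tables named list of [bin_table()]s, one per relocation; names are
#'   the dz values in mm (must include `"0"`).
#' @param statistic one of `"mean"`, `"min"`, `"max"`.
#' @return data.frame with `specimen_id`, `slice_index`, `dz_mm`, `r`,
#'   `p_value`, `n`, `delta_r`; locations with fewer than 3 usable bins are
#'   skipped (recorded in attribute `skipped`).
#' @export
correlation_sweep <- function(tables, statistic = c("mean", "min", "max")) {
  statistic <- match.arg(statistic)
  if (!"0" %in% names(tables)) stop("tables must include the baseline (name \"0\")")
  col <- paste0(statistic, "_wss_pa")
  rows <- list(); skipped <- list()
  base <- as.data.frame(tables[["0"]])
  for (dz in names(tables)) {
    tb <- as.data.frame(tables[[dz]])
    for (loc in unique(paste(tb$specimen_id, tb$slice_index, sep = "\r"))) {
      parts <- strsplit(loc, "\r")[[1]]
      g <- tb[tb$specimen_id == parts[1] & tb$slice_index == as.integer(parts[2]), ]
      g <- g[g$included & !is.na(g[[col]]) & !is.na(g$plaque_thickness_mm), ]
      res <- if (nrow(g) >= 3)
        tryCatch(pearson_correlation(g[[col]], g$plaque_thickness_mm, statistic),
                 error = function(e) NULL) else NULL
      if (is.null(res)) {  # too few bins or zero variance: location skipped
        skipped[[length(skipped) + 1]] <- data.frame(
          specimen_id = parts[1], slice_index = as.integer(parts[2]), dz_mm = dz)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = parts[1], slice_index = as.integer(parts[2]),
        dz_mm = as.numeric(dz), r = res$r, p_value = res$p_value, n = res$n)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen_id = character(), slice_index = integer(),
                      dz_mm = numeric(), r = numeric(), p_value = numeric(),
                      n = integer(), delta_r = numeric())
  if (nrow(out)) {
    base_r <- out[out$dz_mm == 0, ]
    idx <- match(paste(out$specimen_id, out$slice_index),
                 paste(base_r$specimen_id, base_r$slice_index))
    out$delta_r <- out$r - base_r$r[idx]
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}
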