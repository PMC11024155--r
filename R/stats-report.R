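#' Per-disc insulin density
#'
#' Computes the tissue volume (autofluorescence mask voxels; enclosed
#' vessel/duct lumens are empty space and are not counted, while their
#' walls are) and the insulin-positive volume density. Lumens are detected
#' as the morphological closing difference: cavities filled by closing the
#' AF mask that do not connect to the outside; open boundary notches count
#' as outside, not lumen.
#'
#' @param grid a [voxel_grid()] with an `AF` channel.
#' @param ins_labels a [label_volume()] of the insulin segmentation.
#' @param af_threshold strict AF cut-off for the tissue mask.
#' @param closing_um closing ball radius (must exceed the lumen radius for
#'   lumens to be detected).
#' @param disc_id identifier carried into the summary.
#' @return a one-row tibble: `disc_id`, `tissue_volume_um3`,
#'   `lumen_volume_um3`, `ins_volume_um3`, `ins_density`, `n_islets`.
#' @export
disc_density <- function(grid, ins_labels, af_threshold = 10, closing_um = 50,
                         disc_id = 1L) {
  af <- get_channel(grid, "AF")
  vox <- grid$voxel_size
  vv <- voxel_volume(vox)
  raw <- af > af_threshold
  storage.mode(raw) <- "integer"
  lab <- cpp_label3d(raw, 26L)
  n <- attr(lab, "n_labels")
  if (n == 0) abort("zero tissue volume: no AF voxels above threshold")
  counts <- tabulate(lab[lab > 0L], nbins = n)
  main <- array(lab == which.max(counts), dim = dim(af))
  closed <- binary_close(main, closing_um, vox)

  fill <- closed & !main
  storage.mode(fill) <- "integer"
  flab <- cpp_label3d(fill, 6L)
  nf <- attr(flab, "n_labels")
  lumen_voxels <- 0
  if (nf > 0) {
    outside <- !closed
    storage.mode(outside) <- "integer"
    open_notch <- cpp_label_adjacent(flab, outside, nf)
    enclosed <- which(!open_notch)
    if (length(enclosed)) {
      fcounts <- tabulate(flab[flab > 0L], nbins = nf)
      lumen_voxels <- sum(fcounts[enclosed])
    }
  }
  tissue_vol <- (sum(closed) - sum(fill)) * vv  # = AF+ wall/parenchyma voxels
  ins_vol <- sum(ins_labels$labels > 0L) * vv
  tibble(
    disc_id = disc_id,
    tissue_volume_um3 = tissue_vol,
    lumen_volume_um3 = lumen_voxels * vv,
    ins_volume_um3 = ins_vol,
    ins_density = ins_vol / tissue_vol,
    n_islets = ins_labels$n_labels
  )
}

#' Robust outlier removal (ROUT) for column data
#'
#' Constant-location reduction of the robust-regression-and-outlier-removal
#' procedure: the robust centre is the median; the robust scale (RSDR) is
#' the 68.27th percentile of the absolute residuals with the small-sample
#' correction `n / (n - 1)`; each point receives a t-like statistic and a
#' two-sided p-value; outliers are flagged by a step-down
#' false-discovery-rate test at rate `Q`, from the most extreme point
#' inward, with at most 30% of points removable.
#'
#' @param values numeric vector (n >= 4 for any removal).
#' @param Q false-discovery rate (default 0.01, i.e. 1%); `Q = 0` never
#'   removes anything.
#' @return a list of class `rout`: `kept`, `removed`, `outlier` (logical),
#'   `center`, `rsdr`, `Q`, `n`.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  out <- list(kept = values, removed = numeric(0),
              outlier = rep(FALSE, n), center = median(values),
              rsdr = NA_real_, Q = Q, n = n)
  class(out) <- "rout"
  if (n < 4) {
    warn("ROUT requires n >= 4; nothing removed")
    return(out)
  }
  resid <- values - out$center
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  out$rsdr <- rsdr
  if (Q <= 0 || rsdr <= 0) return(out)
  tstat <- abs(resid) / rsdr
  p <- 2 * pt(-tstat, df = n - 1)
  ord <- order(p)  # most extreme first
  max_out <- floor(0.3 * n)
  flag <- rep(FALSE, n)
  for (i in seq_len(max_out)) {
    alpha_i <- Q * (n - i + 1) / n
    if (p[ord[i]] < alpha_i) flag[ord[i]] <- TRUE else break
  }
  out$outlier <- flag
  out$kept <- values[!flag]
  out$removed <- values[flag]
  out
}

#' @export
print.rout <- function(x, ...) {
  cat(sprintf("ROUT (Q = %g%%): %d of %d value(s) flagged as outliers\n",
              100 * x$Q, length(x$removed), x$n))
  if (length(x$removed)) cat(" removed:", format(x$removed), "\n")
  invisible(x)
}

star_code <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Normality-gated paired comparison
#'
#' Applies a Shapiro-Wilk normality test to each vector at `alpha`; when
#' both pass, a two-sided paired t-test is used, otherwise the Wilcoxon
#' matched-pairs signed-rank test. P-values carry the star convention
#' P > 0.05 (ns), <= 0.05 (*), <= 0.01 (**), <= 0.001 (***),
#' <= 0.0001 (****).
#'
#' @param x,y equal-length paired vectors, n >= 3.
#' @param alpha normality-test level (default 0.05).
#' @return a list of class `paired_compare`: `method`, `statistic`,
#'   `p_value`, `stars`, `n`, `normal`, `shapiro_p`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length)")
  n <- length(x)
  if (n < 3) abort("paired comparison requires n >= 3")
  shapiro_p <- vapply(list(x = x, y = y), function(v) {
    if (length(unique(v)) == 1L) return(1)  # constant column: trivially non-skewed
    tryCatch(shapiro.test(v)$p.value, error = function(e) 1)
  }, numeric(1))
  normal <- all(shapiro_p > alpha)
  d <- x - y
  if (all(d == 0)) {
    res <- list(method = if (normal) "paired t-test" else
                  "Wilcoxon matched-pairs signed-rank test",
                statistic = 0, p_value = 1)
  } else if (normal) {
    tt <- t.test(x, y, paired = TRUE)
    res <- list(method = "paired t-test",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE))
    res <- list(method = "Wilcoxon matched-pairs signed-rank test",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(c(res, list(stars = star_code(res$p_value), n = n,
                        normal = normal, shapiro_p = shapiro_p)),
            class = "paired_compare")
}

#' @export
print.paired_compare <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %d\n",
              x$method, x$statistic, x$p_value, x$stars, x$n))
  invisible(x)
}

#' Build a machine-readable analysis report
#'
#' Collects per-disc densities, per-region pooled densities, size-bin
#' histograms, composition fractions and spectra, and k-NN summaries into
#' one schema-versioned bundle, together with the fully resolved
#' configuration and seeds so a run can be reproduced exactly.
#'
#' @param discs tibble of per-disc summaries ([disc_density()] rows).
#' @param islets classified, measured islet table.
#' @param config the resolved pipeline configuration (list).
#' @param knn optional [knn_distances()] table.
#' @param spectrum optional [composition_spectrum()] table.
#' @param bins optional [bin_histograms()] table.
#' @return a list of class `islet_report`.
#' @export
build_report <- function(discs, islets, config = list(), knn = NULL,
                         spectrum = NULL, bins = NULL) {
  if (nrow(discs) < 1) abort("at least one disc summary is required")
  need <- c("disc_id", "tissue_volume_um3", "ins_volume_um3", "ins_density",
            "n_islets")
  missing_cols <- setdiff(need, names(discs))
  if (length(missing_cols))
    abort(sprintf("disc summaries violate the report schema; missing field(s): %s",
                  paste(missing_cols, collapse = ", ")))
  if (any(discs$tissue_volume_um3 <= 0) ||
      any(discs$ins_density < 0 | discs$ins_density > 1))
    abort("disc summaries violate the report schema: tissue_volume_um3 must be positive and ins_density in [0, 1]")
  no_objects <- nrow(islets) == 0
  pooled_density <- sum(discs$ins_volume_um3) / sum(discs$tissue_volume_um3)
  regions <- if (!no_objects && "region" %in% names(islets)) {
    dplyr::group_by(islets, .data$region) |>
      dplyr::summarise(n_islets = dplyr::n(),
                       ins_volume_um3 = sum(.data$volume_um3), .groups = "drop")
  } else NULL
  comp <- if (!no_objects && "comp_class" %in% names(islets)) {
    tab <- table(islets$comp_class)
    tibble(comp_class = names(tab), n = as.integer(tab),
           fraction = as.integer(tab) / sum(tab))
  } else NULL
  size_cat <- if (!no_objects && "size_category" %in% names(islets)) {
    dplyr::group_by(islets, .data$size_category) |>
      dplyr::summarise(n = dplyr::n(), volume_um3 = sum(.data$volume_um3),
                       .groups = "drop")
  } else NULL
  report <- list(
    schema_version = "1.0",
    config = config,
    flags = list(no_objects = no_objects),
    discs = discs,
    pooled = list(ins_density = pooled_density,
                  n_islets = sum(discs$n_islets),
                  tissue_volume_um3 = sum(discs$tissue_volume_um3),
                  ins_volume_um3 = sum(discs$ins_volume_um3)),
    regions = regions,
    composition = comp,
    size_categories = size_cat,
    size_bins = bins,
    composition_spectrum = spectrum,
    knn = if (!is.null(knn)) knn_summary(knn) else NULL,
    islets = islets
  )
  class(report) <- "islet_report"
  report
}

#' Write a report bundle to disk
#'
#' Emits `report.json` plus one CSV per table. Output is byte-stable: the
#' same report writes the same bytes (no timestamps).
#'
#' @param report an `islet_report` from [build_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "islet_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  for (nm in c("discs", "regions", "composition", "size_categories",
               "size_bins", "composition_spectrum", "knn", "islets")) {
    tab <- report[[nm]]
    if (!is.null(tab) && is.data.frame(tab))
      readr::write_csv(as_tibble(tab), file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
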