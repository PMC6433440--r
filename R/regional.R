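#' AHA 17-segment partition of the left ventricle
#'
#' Labels every myocardial voxel with one of the 17 standard AHA segments:
#' the cavity-containing slices are split along the long axis into equal
#' basal / mid-cavity / apical thirds (remainder slices assigned base
#' first), the basal and mid rings into six 60-degree sectors (segments
#' 1-6 and 7-12), the apical ring into four 90-degree sectors (13-16), and
#' the closed apical cap beyond the cavity becomes the apex (segment 17).
#' Sector boundaries are measured counterclockwise from the configured
#' angular origin.
#'
#' @param geom an `lv_geometry`.
#' @param origin angular origin in degrees (default: the geometry's).
#' @return object of class `aha_segmentation`: list with `labels` (integer
#'   array, `NA` outside the wall), `regions` (data.frame mapping segment
#'   to region), `slice_groups`.
#' @export
aha_segment <- function(geom, origin = geom$aha_origin %||% 0) {
  stopifnot(inherits(geom, "lv_geometry"))
  dims <- dim(geom$mask)
  cavity <- geom$cavity_slices
  if (is.null(cavity)) {
    has_cavity <- vapply(seq_len(dims[3]), function(z) {
      sl <- geom$mask[, , z]
      any(sl) && !all(sl[is.finite(sl)])  # annular slice heuristic
    }, logical(1))
    cavity <- which(has_cavity)
  }
  if (length(cavity) < 3L) stop("need at least 3 cavity slices")
  # base = highest slice index (long axis runs apex -> base)
  ord <- sort(cavity, decreasing = TRUE)
  n <- length(ord)
  q <- n %/% 3L; r <- n %% 3L
  sizes <- c(basal = q + (r >= 1L), mid = q + (r >= 2L), apical = q)
  basal <- ord[seq_len(sizes["basal"])]
  mid <- ord[sizes["basal"] + seq_len(sizes["mid"])]
  apical <- ord[sizes["basal"] + sizes["mid"] + seq_len(sizes["apical"])]

  labels <- array(NA_integer_, dims)
  sector <- function(z, n_sec, base_label) {
    sl <- geom$mask[, , z]
    if (!any(sl)) return()
    idx <- which(sl, arr.ind = TRUE)
    ang <- rad2deg(atan2(idx[, 2] - geom$centers[z, 2],
                         idx[, 1] - geom$centers[z, 1]))
    rel <- (ang - origin) %% 360
    lab <- base_label + pmin(n_sec - 1L, floor(rel / (360 / n_sec)))
    v <- labels[, , z]
    v[sl] <- as.integer(lab)
    labels[, , z] <<- v
  }
  for (z in basal) sector(z, 6L, 1L)
  for (z in mid) sector(z, 6L, 7L)
  for (z in apical) sector(z, 4L, 13L)
  cap <- setdiff(which(apply(geom$mask, 3, any)), cavity)
  for (z in cap) {
    v <- labels[, , z]
    v[geom$mask[, , z]] <- 17L
    labels[, , z] <- v
  }

  regions <- data.frame(
    segment = 1:17,
    region = c(rep("basal", 6), rep("mid-cavity", 6), rep("apical", 4),
               "apex"),
    stringsAsFactors = FALSE)
  structure(list(labels = labels, regions = regions,
                 slice_groups = list(basal = basal, mid = mid,
                                     apical = apical, apex = cap)),
            class = "aha_segmentation")
}

#' Anisotropy mask
#'
#' Boolean mask of voxels whose FA meets the anisotropy threshold (default
#' 0.1, the conventional cutoff separating myocardium from isotropic or
#' noise-dominated voxels before fiber-based analysis).
#'
#' @param fa_map FA array.
#' @param threshold minimum FA retained.
#' @return logical array; `NA` FA values are excluded.
#' @export
fa_mask <- function(fa_map, threshold = 0.1) {
  m <- !is.na(fa_map) & fa_map >= threshold
  array(m, dim(fa_map))
}

.layer_names <- c("endocardial", "sub-endocardial", "mid-wall",
                  "sub-epicardial", "epicardial")

#' Transmural helix-angle profiles
#'
#' Bins myocardial voxels by transmural depth into five equal-width layers
#' (endocardial, sub-endocardial, mid-wall, sub-epicardial, epicardial) and
#' reports the layer mean and SD of the helix angle per region (apical,
#' mid-cavity, basal; the apex has no ring geometry and is excluded).
#'
#' @param ha_map helix-angle array in degrees.
#' @param geom an `lv_geometry` supplying the transmural-depth map.
#' @param seg an `aha_segmentation`.
#' @param regions regions to profile.
#' @param n_layers number of equal-depth layers.
#' @param valid optional logical array restricting the voxels used.
#' @return object of class `transmural_profile`: data.frame with columns
#'   `region`, `layer`, `layer_name`, `depth_mid` (percent), `mean`, `sd`,
#'   `n`.  Empty layers carry `NA` means and are skipped by
#'   [transmural_gradients()].
#' @export
transmural_profiles <- function(ha_map, geom, seg,
                                regions = c("apical", "mid-cavity", "basal"),
                                n_layers = 5L, valid = NULL) {
  stopifnot(inherits(geom, "lv_geometry"), inherits(seg, "aha_segmentation"))
  depth <- geom$depth
  breaks <- seq(0, 1, length.out = n_layers + 1L)
  mids <- 100 * (head(breaks, -1L) + tail(breaks, -1L)) / 2
  out <- list()
  for (reg in regions) {
    segs <- seg$regions$segment[seg$regions$region == reg]
    sel <- !is.na(seg$labels) & (seg$labels %in% segs) &
      !is.na(ha_map) & !is.na(depth)
    if (!is.null(valid)) sel <- sel & valid
    if (!any(sel)) stop(sprintf("region '%s' contains no usable voxels", reg))
    d <- depth[sel]
    h <- ha_map[sel]
    layer <- pmin(n_layers, findInterval(d, breaks, rightmost.closed = TRUE))
    mu <- sdv <- nn <- rep(NA_real_, n_layers)
    for (l in seq_len(n_layers)) {
      hl <- h[layer == l]
      nn[l] <- length(hl)
      if (length(hl)) {
        mu[l] <- mean(hl)
        sdv[l] <- stats::sd(hl)
      }
    }
    out[[reg]] <- data.frame(region = reg, layer = seq_len(n_layers),
                             layer_name = if (n_layers == 5L) .layer_names
                                          else paste0("layer", seq_len(n_layers)),
                             depth_mid = mids, mean = mu, sd = sdv, n = nn,
                             stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("transmural_profile", "data.frame"))
}

#' Average transmural profiles across hearts
#'
#' @param profiles list of `transmural_profile` objects (one per heart).
#' @return a `transmural_profile` whose `mean` is the across-heart mean of
#'   layer means and whose `sd` is the across-heart SD of layer means.
#' @export
average_profiles <- function(profiles) {
  all <- do.call(rbind, profiles)
  agg <- stats::aggregate(mean ~ region + layer + layer_name + depth_mid,
                          data = all, FUN = function(x) c(m = mean(x),
                                                          s = stats::sd(x),
                                                          n = length(x)))
  out <- data.frame(region = agg$region, layer = agg$layer,
                    layer_name = agg$layer_name, depth_mid = agg$depth_mid,
                    mean = agg$mean[, "m"], sd = agg$mean[, "s"],
                    n = agg$mean[, "n"], stringsAsFactors = FALSE)
  out <- out[order(out$region, out$layer), ]
  structure(out, class = c("transmural_profile", "data.frame"))
}

#' Transmural helix-angle gradients
#'
#' Differences of adjacent layer means divided by the depth-midpoint
#' spacing, in degrees per percent of transmural depth, plus the total
#' transmural gradient (epicardial minus endocardial layer mean over the
#' depth span).  Empty layers are skipped.
#'
#' @param profile a `transmural_profile`.
#' @return data.frame with columns `region`, `from_layer`, `to_layer`,
#'   `gradient` (deg per percent depth) and a `"total"` row per region.
#' @export
transmural_gradients <- function(profile) {
  out <- list()
  for (reg in unique(profile$region)) {
    p <- profile[profile$region == reg & !is.na(profile$mean), ]
    if (nrow(p) < 2L) stop("need at least two non-empty layers")
    p <- p[order(p$layer), ]
    g <- diff(p$mean) / diff(p$depth_mid)
    out[[reg]] <- rbind(
      data.frame(region = reg, from_layer = head(p$layer, -1L),
                 to_layer = tail(p$layer, -1L), gradient = g,
                 stringsAsFactors = FALSE),
      data.frame(region = reg, from_layer = p$layer[1],
                 to_layer = p$layer[nrow(p)],
                 gradient = (p$mean[nrow(p)] - p$mean[1]) /
                   (p$depth_mid[nrow(p)] - p$depth_mid[1]),
                 stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$type <- ifelse(res$to_layer - res$from_layer == 1L, "adjacent", "total")
  res
}

#' Per-segment and per-region diffusion statistics
#'
#' Medians of ADC, FA, |E2A| and the primary eigenvector components over
#' the valid voxels of each AHA segment, with region aggregates (mean of
#' the constituent segment medians) for apex, apical, mid-cavity, basal and
#' the whole LV.  The midpoint convention is used for even-count medians
#' (the default of [stats::median()]).
#'
#' @param maps named list of arrays; recognized names: `adc`, `fa`,
#'   `abs_e2a`, `e1` (a `dims x 3` eigenvector field, reported as
#'   component medians `e11`, `e12`, `e13`).
#' @param seg an `aha_segmentation`.
#' @param valid optional logical array restricting the voxels used.
#' @return object of class `regional_stats`: list with `segments` (one row
#'   per segment) and `regions` (aggregates incl. an `"lv"` row).  Empty
#'   segments are kept with `NA` values and a warning.
#' @export
segment_statistics <- function(maps, seg, valid = NULL) {
  stopifnot(inherits(seg, "aha_segmentation"))
  labels <- seg$labels
  scalar_names <- intersect(names(maps), c("adc", "fa", "abs_e2a"))
  cols <- scalar_names
  if ("e1" %in% names(maps)) cols <- c(cols, c("e11", "e12", "e13"))

  segments <- data.frame(segment = 1:17,
                         region = seg$regions$region,
                         n_voxels = 0L, stringsAsFactors = FALSE)
  for (cn in cols) segments[[cn]] <- NA_real_

  for (s in 1:17) {
    sel <- !is.na(labels) & labels == s
    if (!is.null(valid)) sel <- sel & valid
    segments$n_voxels[s] <- sum(sel)
    if (!any(sel)) next
    for (cn in scalar_names)
      segments[[cn]][s] <- stats::median(maps[[cn]][sel], na.rm = TRUE)
    if ("e1" %in% names(maps)) {
      for (k in 1:3)
        segments[[paste0("e1", k)]][s] <-
          stats::median(maps$e1[, , , k][sel], na.rm = TRUE)
    }
  }
  if (any(segments$n_voxels == 0L))
    warning("empty segments recorded as missing: ",
            paste(segments$segment[segments$n_voxels == 0L], collapse = ", "))

  agg_region <- function(rows, name) {
    d <- segments[rows, , drop = FALSE]
    out <- data.frame(region = name, n_segments = sum(d$n_voxels > 0L),
                      n_voxels = sum(d$n_voxels), stringsAsFactors = FALSE)
    for (cn in cols) out[[cn]] <- mean(d[[cn]], na.rm = TRUE)
    out
  }
  regions <- rbind(
    agg_region(segments$region == "apex", "apex"),
    agg_region(segments$region == "apical", "apical"),
    agg_region(segments$region == "mid-cavity", "mid-cavity"),
    agg_region(segments$region == "basal", "basal"),
    agg_region(rep(TRUE, 17), "lv"))
  structure(list(segments = segments, regions = regions),
            class = "regional_stats")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences, following Wilcoxon's
#' original treatment of ties at zero: zero differences are dropped before
#' ranking.  The exact null distribution is used for up to 25 non-zero
#' pairs when the absolute differences are tie-free; otherwise the normal
#' approximation is used.  All-zero differences (identical arms) give
#' p = 1.
#'
#' @param x,y paired measurements (equal length).
#' @return list with `statistic` (signed-rank V) and `p` (two-sided).
#' @export
wilcoxon_paired <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]            # Wilcoxon's rule: drop zero differences
  if (!length(nz))
    return(list(statistic = NA_real_, p = 1))
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  w <- suppressWarnings(stats::wilcox.test(nz, exact = exact))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Compare diffusion statistics between two protocols
#'
#' Implements the paired comparison procedure used to validate one
#' acquisition against a reference: a two-sided paired Wilcoxon signed-rank
#' test on per-heart regional values of each metric (exact null
#' distribution for n <= 25 paired hearts, zero differences dropped), and a
#' per-segment percent-deviation "bias range" of the across-heart segment
#' medians relative to the reference.
#'
#' @param test,ref data.frames of per-heart segment statistics with columns
#'   `heart`, `segment`, `region` and one column per metric (rbind the
#'   `$segments` tables of [segment_statistics()] with a `heart` column
#'   added).
#' @param metrics metric columns to compare.
#' @param bias_metrics metrics entering the bias range (deviations of
#'   segment medians).
#' @param alpha significance level.
#' @return object of class `cdti_comparison`: list with `tests` (metric,
#'   region, n hearts, statistic, p value, significance flag), `bias`
#'   (per-segment percent deviations) and `bias_range` (min/max percent
#'   deviation over the 17 segments, per metric).
#' @export
compare_to_reference <- function(test, ref,
                                 metrics = c("adc", "fa", "abs_e2a"),
                                 bias_metrics = c("adc", "fa"),
                                 alpha = 0.05) {
  hearts_t <- sort(unique(test$heart))
  hearts_r <- sort(unique(ref$heart))
  if (!identical(hearts_t, hearts_r)) {
    missing <- c(setdiff(hearts_t, hearts_r), setdiff(hearts_r, hearts_t))
    stop("unpaired hearts: ", paste(missing, collapse = ", "))
  }
  if (length(hearts_t) < 5L)
    stop("need at least 5 paired hearts")

  region_value <- function(d, metric) {
    # per-heart region aggregate = mean of the heart's segment medians
    v <- stats::aggregate(d[[metric]],
                          by = list(heart = d$heart, region = d$region),
                          FUN = mean, na.rm = TRUE)
    lv <- stats::aggregate(d[[metric]], by = list(heart = d$heart),
                           FUN = mean, na.rm = TRUE)
    lv$region <- "lv"
    rbind(v, lv[, c("heart", "region", "x")])
  }

  tests <- list()
  for (m in metrics) {
    vt <- region_value(test, m)
    vr <- region_value(ref, m)
    for (reg in unique(vt$region)) {
      xt <- vt$x[vt$region == reg][order(vt$heart[vt$region == reg])]
      xr <- vr$x[vr$region == reg][order(vr$heart[vr$region == reg])]
      res <- wilcoxon_paired(xt, xr)
      tests[[length(tests) + 1L]] <-
        data.frame(metric = m, region = reg, n = length(xt),
                   statistic = res$statistic, p_value = res$p,
                   significant = is.finite(res$p) && res$p < alpha,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)

  seg_median <- function(d, metric) {
    agg <- stats::aggregate(d[[metric]], by = list(segment = d$segment),
                            FUN = stats::median, na.rm = TRUE)
    stats::setNames(agg$x, agg$segment)
  }
  bias <- list()
  for (m in bias_metrics) {
    mt <- seg_median(test, m)
    mr <- seg_median(ref, m)
    segs <- intersect(names(mt), names(mr))
    dev <- 100 * abs(mt[segs] - mr[segs]) / mr[segs]
    bias[[m]] <- data.frame(metric = m, segment = as.integer(segs),
                            percent_deviation = unname(dev),
                            stringsAsFactors = FALSE)
  }
  bias <- do.call(rbind, c(bias, make.row.names = FALSE))
  bias_range <- do.call(rbind, lapply(split(bias, bias$metric), function(d)
    data.frame(metric = d$metric[1], min = min(d$percent_deviation),
               max = max(d$percent_deviation), stringsAsFactors = FALSE)))
  structure(list(tests = tests, bias = bias, bias_range = bias_range,
                 alpha = alpha),
            class = "cdti_comparison")
}
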