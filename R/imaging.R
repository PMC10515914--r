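#' Per-nucleus SON imaging measurements
#'
#' Nucleus segmentation from a DAPI channel, per-nucleus SON intensity and
#' speckle-object measurements, 4-bin radial distribution of SON signal,
#' per-sample aggregation and median-split survival ranking of
#' measurements.
#'
#' @name nuclear_imaging
NULL

#' Maximum projection of an image stack
#'
#' @param stack 3-d array (x, y, z) or a list of matrices.
#' @return Pixelwise maximum as a matrix.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2) return(stack)
  apply(stack, c(1, 2), max)
}

#' Segment nuclei from a DAPI image
#'
#' Global Otsu threshold on the smoothed image, hole filling, connected
#' component labeling, then removal of objects below the minimum area or
#' touching the image border.
#'
#' @param dapi 2-d numeric matrix (any intensity scale).
#' @param min_area Minimum object area in pixels.
#' @param smooth_sigma Gaussian smoothing sigma (px) before thresholding.
#' @return list: \code{labels} (integer matrix, 0 = background, labels
#'   renumbered 1..n) and \code{nuclei} (data.frame: label, area, cx, cy).
#' @export
segment_nuclei <- function(dapi, min_area = 50, smooth_sigma = 2) {
  if (length(dapi) == 0) stop("empty image")
  rng <- range(dapi)
  if (rng[2] == rng[1]) {
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                nuclei = data.frame(label = integer(0), area = numeric(0),
                                    cx = numeric(0), cy = numeric(0))))
  }
  img <- EBImage::Image((dapi - rng[1]) / (rng[2] - rng[1]))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  th <- EBImage::otsu(sm)
  mask <- EBImage::fillHull(sm > th)
  lab <- EBImage::bwlabel(mask)
  m <- as.matrix(EBImage::imageData(lab))
  border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  keep <- setdiff(seq_len(max(m)), border)
  areas <- tabulate(m, nbins = max(max(m), 1))
  keep <- keep[areas[keep] >= min_area]
  out <- matrix(0L, nrow(m), ncol(m))
  nuclei <- data.frame(label = integer(0), area = numeric(0),
                       cx = numeric(0), cy = numeric(0))
  for (i in seq_along(keep)) {
    px <- which(m == keep[i], arr.ind = TRUE)
    out[px] <- i
    nuclei <- rbind(nuclei, data.frame(label = i, area = nrow(px),
                                       cx = mean(px[, 1]), cy = mean(px[, 2])))
  }
  list(labels = out, nuclei = nuclei)
}

#' Radial distribution of SON signal within one nucleus
#'
#' Each pixel of the mask gets a normalized radial coordinate
#' r = 1 - d_edge / max(d_edge) from the Euclidean distance-to-background
#' transform (r = 0 at the most interior pixel, r -> 1 at the edge). The
#' nucleus is divided into \code{n_bins} concentric bins of equal
#' normalized-distance width (bin 1 = most central; the last bin is closed
#' at 1) and the fraction of SON intensity per bin is returned. For a
#' uniform signal on an ideal disk with 4 bins the fractions approach the
#' annulus areas (1/16, 3/16, 5/16, 7/16).
#'
#' @param mask Logical matrix (single nucleus) or integer label matrix plus
#'   \code{label}.
#' @param son SON intensity matrix (same shape).
#' @param n_bins Number of concentric bins (default 4).
#' @param label Nucleus label when \code{mask} is a label matrix.
#' @return Numeric vector f1..fn (sums to 1), or all-NA with attribute
#'   \code{flagged = TRUE} when the nucleus has zero SON signal.
#' @export
radial_distribution <- function(mask, son, n_bins = 4, label = NULL) {
  if (!is.logical(mask)) {
    if (is.null(label)) stop("label required for a label matrix")
    mask <- mask == label
  }
  if (!any(mask)) stop("empty nucleus mask")
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  dmax <- max(dm[mask])
  r <- 1 - dm[mask] / dmax
  bin <- pmin(floor(r * n_bins) + 1L, n_bins)
  s <- son[mask]
  tot <- sum(s)
  if (tot <= 0) {
    out <- rep(NA_real_, n_bins)
    attr(out, "flagged") <- TRUE
    names(out) <- paste0("f", seq_len(n_bins))
    return(out)
  }
  f <- vapply(seq_len(n_bins), function(b) sum(s[bin == b]) / tot, numeric(1))
  names(f) <- paste0("f", seq_len(n_bins))
  f
}

# Otsu threshold of an intensity vector (between-class variance maximizer);
# used for per-nucleus speckle calling where the pixel set is not a full
# rectangular image
.otsu_vector <- function(v, levels = 256) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * levels) + 1L,
                     levels), nbins = levels)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * (rng[2] - rng[1])
  w1 <- cumsum(w); mu <- cumsum(w * mids); mu_t <- mu[levels]
  bc <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' Call speckle objects within one nucleus
#'
#' Per-nucleus Otsu threshold on SON intensity inside the mask; connected
#' components of at least 2 px are speckles; extra-large (XL) speckles
#' exceed the area threshold. A nucleus whose within-mask SON contrast is
#' degenerate (constant) is flagged low-contrast with zero speckles.
#'
#' @param mask Logical nucleus mask (or label matrix plus \code{label}).
#' @param son SON intensity matrix.
#' @param xl_area_threshold XL speckle area threshold (px).
#' @param label Nucleus label when \code{mask} is a label matrix.
#' @return list: \code{count}, \code{total_area}, \code{xl_fraction},
#'   \code{areas}, \code{low_contrast}.
#' @export
call_speckles <- function(mask, son, xl_area_threshold = 50, label = NULL) {
  if (!is.logical(mask)) {
    if (is.null(label)) stop("label required for a label matrix")
    mask <- mask == label
  }
  if (!any(mask)) stop("empty nucleus mask")
  v <- son[mask]
  if (max(v) == min(v))
    return(list(count = 0L, total_area = 0, xl_fraction = NA_real_,
                areas = numeric(0), low_contrast = TRUE))
  th <- .otsu_vector(v)
  bw <- matrix(0, nrow(son), ncol(son))
  bw[mask] <- as.numeric(son[mask] > th)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw))))
  areas <- tabulate(lab)
  areas <- areas[areas >= 2]
  list(count = length(areas), total_area = sum(areas),
       xl_fraction = if (length(areas))
         mean(areas > xl_area_threshold) else NA_real_,
       areas = areas, low_contrast = FALSE)
}

#' Measure all nuclei in one image pair
#'
#' Segments nuclei from DAPI and computes, per nucleus: area, mean/median
#' DAPI and SON intensity, SON coefficient of variation (contrast proxy),
#' radial fractions f1..f4, speckle count, total speckle area and XL
#' speckle fraction.
#'
#' @param dapi,son Intensity matrices (same shape).
#' @param sample Sample id attached to every row.
#' @param min_area,smooth_sigma Segmentation parameters.
#' @param xl_area_threshold XL speckle threshold (px).
#' @return data.frame, one row per nucleus.
#' @export
measure_nuclei <- function(dapi, son, sample = "sample1", min_area = 50,
                           smooth_sigma = 2, xl_area_threshold = 50) {
  seg <- segment_nuclei(dapi, min_area = min_area,
                        smooth_sigma = smooth_sigma)
  rows <- lapply(seq_len(nrow(seg$nuclei)), function(i) {
    lb <- seg$nuclei$label[i]
    mk <- seg$labels == lb
    f <- radial_distribution(mk, son)
    sp <- call_speckles(mk, son, xl_area_threshold = xl_area_threshold)
    sv <- son[mk]
    data.frame(sample = sample, label = lb, area = seg$nuclei$area[i],
               cx = seg$nuclei$cx[i], cy = seg$nuclei$cy[i],
               dapi_mean = mean(dapi[mk]), dapi_median = stats::median(dapi[mk]),
               son_mean = mean(sv), son_median = stats::median(sv),
               son_total = sum(sv),
               son_cv = stats::sd(sv) / max(mean(sv), 1e-12),
               f1 = f[1], f2 = f[2], f3 = f[3], f4 = f[4],
               speckle_count = sp$count, speckle_area = sp$total_area,
               xl_fraction = sp$xl_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  out
}

#' Per-sample medians of nucleus measurements
#'
#' @param per_nucleus data.frame from [measure_nuclei()] (possibly several
#'   samples row-bound), with a \code{sample} column.
#' @return data.frame: sample, n_nuclei, median of every numeric
#'   measurement.
#' @export
summarize_samples <- function(per_nucleus) {
  if (nrow(per_nucleus) == 0) stop("no nuclei to summarize")
  meas <- setdiff(names(per_nucleus)[vapply(per_nucleus, is.numeric,
                                            logical(1))],
                  c("label", "cx", "cy"))
  out <- lapply(split(per_nucleus, per_nucleus$sample), function(d) {
    med <- vapply(meas, function(m) stats::median(d[[m]], na.rm = TRUE),
                  numeric(1))
    cbind(data.frame(sample = d$sample[1], n_nuclei = nrow(d)),
          as.data.frame(as.list(med)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Median-split survival ranking of imaging measurements
#'
#' For each measurement, samples are split at the median (top vs bottom
#' half), a log-rank test is run via [km_logrank()], and measurements are
#' ranked by -log2(p). Constant measurements are skipped with a warning.
#'
#' @param summaries Per-sample data.frame from [summarize_samples()].
#' @param survival data.frame: sample, time, event.
#' @param measurements Columns to test (default: all numeric measurement
#'   columns).
#' @return data.frame sorted by decreasing -log2(p): measurement, chisq, p,
#'   neg_log2_p.
#' @export
median_split_survival <- function(summaries, survival,
                                  measurements = NULL) {
  if (nrow(summaries) < 4) stop("need at least 4 samples with survival")
  d <- merge(summaries, survival, by = "sample")
  if (is.null(measurements))
    measurements <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                                    logical(1))],
                            "n_nuclei")
  rows <- lapply(measurements, function(m) {
    v <- d[[m]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("skipping constant measurement: ", m)
      return(NULL)
    }
    lab <- ifelse(v > stats::median(v, na.rm = TRUE), "high", "low")
    lab[is.na(v)] <- NA
    if (length(unique(lab[!is.na(lab)])) < 2) {
      warning("skipping degenerate median split for: ", m)
      return(NULL)
    }
    res <- km_logrank(lab, d$time, d$event)
    data.frame(measurement = m, chisq = res$chisq, p = res$p,
               neg_log2_p = -log2(res$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$neg_log2_p), , drop = FALSE]
}
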