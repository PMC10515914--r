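#' Differential DNA-speckle association from windowed SON coverage
#'
#' Sliding-window quantification of SON proximity signal (TSA-seq /
#' Cut&Run style) with background subtraction, a moderated-t differential
#' engine, merging of differential windows into domains, gene
#' classification by association status, per-gene SON signal, thresholded
#' target-gene set definitions and n-tile integration analyses.
#'
#' Coordinates are 0-based half-open internally and in BED output.
#'
#' @name speckle_association
NULL

#' Sliding genomic windows
#'
#' Windows of the given size slid by 1/10 of the size: starts 0, step,
#' 2*step, ... with end <= chromosome length, i.e.
#' floor((L - size) / step) + 1 windows per chromosome of length L >= size.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp; must be divisible by 10.
#' @return data.frame: chrom, start, end, size.
#' @export
make_windows <- function(chrom_sizes, size) {
  if (size %% 10 != 0) stop("window size must be divisible by 10")
  step <- size %/% 10
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    if (L < size) return(NULL)
    n <- floor((L - size) / step) + 1
    starts <- (seq_len(n) - 1) * step
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  out <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
  rownames(out) <- NULL
  out$size <- rep(size, nrow(out))
  out
}

# per-bin background-subtracted cpm from one coverage/background count pair
.bin_signal_cpm <- function(cov_counts, bg_counts) {
  cpm <- function(x) x / sum(x) * 1e6
  pmax(0, cpm(cov_counts) - cpm(bg_counts))
}

#' Quantify SON signal over windows with background subtraction
#'
#' Per replicate, bin counts are scaled to counts-per-million, the matched
#' background (input/IgG) cpm is subtracted and clamped at zero, and the
#' per-bin signal is summed over each window. Bins must align with the
#' window grid (bin width dividing the window step).
#'
#' @param bins data.frame chrom/start/end of the coverage grid.
#' @param coverage Bins x replicates count matrix.
#' @param background Matching background count matrix.
#' @param windows Windows from [make_windows()] (same genome).
#' @return Windows x replicates signal matrix.
#' @export
quantify_windows <- function(bins, coverage, background, windows) {
  coverage <- as.matrix(coverage); background <- as.matrix(background)
  bw <- unique(bins$end - bins$start)
  if (length(bw) != 1) stop("bins must have uniform width")
  step <- unique(windows$size) %/% 10
  if (any(step %% bw != 0) || any(windows$start %% bw != 0))
    stop("bin grid does not align with the window step")
  sig <- matrix(0, nrow(windows), ncol(coverage),
                dimnames = list(NULL, colnames(coverage)))
  for (r in seq_len(ncol(coverage))) {
    per_bin <- .bin_signal_cpm(coverage[, r], background[, r])
    for (ch in unique(windows$chrom)) {
      bi <- which(bins$chrom == ch)
      wi <- which(windows$chrom == ch)
      cs <- c(0, cumsum(per_bin[bi]))
      i0 <- windows$start[wi] %/% bw          # first bin index (0-based)
      i1 <- windows$end[wi] %/% bw            # one-past-last bin index
      sig[wi, r] <- cs[pmin(i1, length(bi)) + 1L] - cs[i0 + 1L]
    }
  }
  sig
}

#' Differential windows by moderated two-sample t
#'
#' Per window, a two-sample t-statistic on log2(signal + c) with the
#' per-window variance shrunk toward the global median variance with prior
#' degrees of freedom d0 (t df = d0 + n1 + n2 - 2). The median (not the
#' mean) is the shrinkage target because background-subtracted windows near
#' domain boundaries flip between clamped-zero and positive signal across
#' replicates, and their extreme log-scale variances would otherwise
#' dominate the pooled center and destroy power genome-wide. Windows below the
#' minimum mean signal are removed before testing; Benjamini-Hochberg
#' adjustment is applied over all tested windows of the given size.
#'
#' @param windows Windows data.frame (one size).
#' @param signal Windows x replicates matrix from [quantify_windows()].
#' @param condition Factor/character of length ncol(signal) with two levels
#'   (log2 fold change is level2 vs level1, i.e. treatment vs control when
#'   levels are c("control", "treatment")).
#' @param d0 Prior degrees of freedom for variance shrinkage.
#' @param pseudocount Constant c added before log2.
#' @param min_mean_signal Mean-signal filter (cpm units) applied before
#'   testing.
#' @return data.frame: windows columns plus mean_signal, log2fc, t, p, padj,
#'   direction ("decrease"/"increase"/"none"). Filtered windows are absent.
#' @export
differential_windows <- function(windows, signal, condition, d0 = 10,
                                 pseudocount = 1, min_mean_signal = 1) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  n1 <- sum(condition == levels(condition)[1])
  n2 <- sum(condition == levels(condition)[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 replicates per condition")
  mean_signal <- rowMeans(signal)
  keep <- mean_signal >= min_mean_signal
  windows <- windows[keep, , drop = FALSE]
  x <- log2(signal[keep, , drop = FALSE] + pseudocount)
  g1 <- condition == levels(condition)[1]
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, !g1, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !g1, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  s2_mod <- (d0 * stats::median(s2) + df * s2) / (d0 + df)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  tt <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- pmin(2 * stats::pt(abs(tt), df = d0 + df, lower.tail = FALSE), 1)
  out <- windows
  out$mean_signal <- mean_signal[keep]
  out$log2fc <- delta
  out$t <- tt
  out$p <- p
  out$padj <- stats::p.adjust(p, method = "BH")
  out$direction <- ifelse(out$log2fc < 0, "decrease",
                          ifelse(out$log2fc > 0, "increase", "none"))
  rownames(out) <- NULL
  out
}

#' Merge differential windows of both sizes into domains
#'
#' Windows passing the adjusted-p threshold with the requested direction
#' are pooled across the two window sizes and merged when overlapping or
#' book-ended (gap 0); the domain padj is the minimum member padj. The
#' result is independent of input order and idempotent.
#'
#' @param window_stats_50k,window_stats_100k [differential_windows()]
#'   outputs (either may be NULL).
#' @param padj_threshold Windows with padj < threshold are merged.
#' @param direction "decrease" or "increase".
#' @return data.frame: chrom, start, end, direction, padj, n_windows.
#' @export
merge_domains <- function(window_stats_50k, window_stats_100k = NULL,
                          padj_threshold = 0.01, direction = "decrease") {
  ws <- rbind(window_stats_50k, window_stats_100k)
  ws <- ws[!is.na(ws$padj) & ws$padj < padj_threshold &
             ws$direction == direction, , drop = FALSE]
  if (nrow(ws) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      padj = numeric(0), n_windows = integer(0)))
  gr <- GenomicRanges::GRanges(ws$chrom,
                               IRanges::IRanges(ws$start + 1, ws$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(red, gr)
  padj <- vapply(seq_along(red), function(i)
    min(ws$padj[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]),
    numeric(1))
  nw <- as.integer(table(factor(S4Vectors::queryHits(ov),
                                levels = seq_along(red))))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    direction = direction, padj = padj, n_windows = nw,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify genes by speckle-association status
#'
#' A gene overlaps a domain if at least 1 bp of its span (or its TSS in
#' "tss" mode) intersects it. A gene is \emph{associating} if it overlaps a
#' decreasing domain with padj below \code{assoc_padj} in either method;
#' \emph{non-associating} if every overlap (in both methods) has padj above
#' \code{nonassoc_padj}, or it overlaps no differential domain; otherwise
#' \emph{ambiguous}.
#'
#' @param domains_tsa,domains_cnr Decreasing-domain tables (chrom, start,
#'   end, padj), e.g. [merge_domains()] output at a permissive threshold or
#'   window-level stats; either may be NULL.
#' @param genes data.frame: chrom, start, end, gene_id (unique), optional
#'   strand (for "tss" mode).
#' @param assoc_padj,nonassoc_padj Class thresholds.
#' @param mode "span" (default) or "tss".
#' @return data.frame: gene_id, padj_tsa, padj_cnr (min over overlaps; NA if
#'   none), class.
#' @export
classify_genes <- function(domains_tsa, domains_cnr, genes,
                           assoc_padj = 0.01, nonassoc_padj = 0.1,
                           mode = c("span", "tss")) {
  mode <- match.arg(mode)
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (any(genes$end <= genes$start)) stop("malformed gene interval")
  gstart <- genes$start; gend <- genes$end
  if (mode == "tss") {
    strand <- if ("strand" %in% names(genes)) genes$strand else "+"
    tss <- ifelse(strand == "-", genes$end - 1, genes$start)
    gstart <- tss; gend <- tss + 1
  }
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(gstart + 1, gend))
  min_padj <- function(dom) {
    if (is.null(dom) || nrow(dom) == 0) return(rep(NA_real_, length(ggr)))
    dgr <- GenomicRanges::GRanges(dom$chrom,
                                  IRanges::IRanges(dom$start + 1, dom$end))
    ov <- GenomicRanges::findOverlaps(ggr, dgr)
    out <- rep(NA_real_, length(ggr))
    if (length(ov)) {
      agg <- tapply(dom$padj[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), min)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  p_tsa <- min_padj(domains_tsa)
  p_cnr <- min_padj(domains_cnr)
  assoc <- (!is.na(p_tsa) & p_tsa < assoc_padj) |
           (!is.na(p_cnr) & p_cnr < assoc_padj)
  nonassoc <- (is.na(p_tsa) | p_tsa > nonassoc_padj) &
              (is.na(p_cnr) | p_cnr > nonassoc_padj)
  class <- ifelse(assoc, "associating",
                  ifelse(nonassoc, "non-associating", "ambiguous"))
  data.frame(gene_id = genes$gene_id, padj_tsa = p_tsa, padj_cnr = p_cnr,
             class = class, stringsAsFactors = FALSE)
}

#' Per-gene SON signal
#'
#' Mean background-subtracted cpm over the gene span extended by
#' \code{flank_bp} on each side. Replicates are averaged.
#'
#' @param bins,coverage,background As in [quantify_windows()].
#' @param genes Gene table (chrom, start, end, gene_id).
#' @param flank_bp Non-negative flank (default 0).
#' @return Named numeric vector (gene_id -> SON signal).
#' @export
per_gene_son_signal <- function(bins, coverage, background, genes,
                                flank_bp = 0) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  coverage <- as.matrix(coverage); background <- as.matrix(background)
  per_bin <- rowMeans(vapply(seq_len(ncol(coverage)), function(r)
    .bin_signal_cpm(coverage[, r], background[, r]),
    numeric(nrow(coverage))))
  bgr <- GenomicRanges::GRanges(bins$chrom,
                                IRanges::IRanges(bins$start + 1, bins$end))
  chrom_max <- tapply(bins$end, bins$chrom, max)
  s <- pmax(genes$start - flank_bp, 0)
  e <- pmin(genes$end + flank_bp, chrom_max[genes$chrom])
  if (any(genes$start >= chrom_max[genes$chrom]))
    stop("gene outside chromosome bounds")
  ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(s + 1, e))
  ov <- GenomicRanges::findOverlaps(ggr, bgr)
  val <- tapply(per_bin[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov),
                       levels = seq_along(ggr)), mean)
  stats::setNames(as.numeric(val), genes$gene_id)
}

#' Thresholded target-gene sets from differential-expression tables
#'
#' Set algebra over DE tables (columns gene, log2fc, p, padj). Each rule
#' selects genes from one or more tables by thresholds and combines tables
#' by union or intersection; an optional \code{intersect_with} applies a
#' second rule as a filter (e.g. a tumor-up requirement).
#'
#' @param de_tables Named list of DE data.frames.
#' @param rules Named list; each element a list with fields \code{tables}
#'   (names into de_tables), optional \code{padj_lt}, \code{p_lt},
#'   \code{lfc_gt}, \code{lfc_lt}, \code{combine} ("union"/"intersect",
#'   default union), optional \code{intersect_with} (another rule).
#' @return Named list of character vectors (gene sets).
#' @export
define_target_gene_sets <- function(de_tables, rules) {
  pick <- function(tab, rule) {
    need <- c("gene", if (!is.null(rule$padj_lt)) "padj",
              if (!is.null(rule$p_lt)) "p",
              if (!is.null(rule$lfc_gt) || !is.null(rule$lfc_lt)) "log2fc")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("DE table missing column: ", miss[1])
    keep <- rep(TRUE, nrow(tab))
    if (!is.null(rule$padj_lt)) keep <- keep & !is.na(tab$padj) &
        tab$padj < rule$padj_lt
    if (!is.null(rule$p_lt)) keep <- keep & !is.na(tab$p) & tab$p < rule$p_lt
    if (!is.null(rule$lfc_gt)) keep <- keep & tab$log2fc > rule$lfc_gt
    if (!is.null(rule$lfc_lt)) keep <- keep & tab$log2fc < rule$lfc_lt
    unique(tab$gene[keep])
  }
  eval_rule <- function(rule) {
    sets <- lapply(rule$tables, function(nm) {
      if (!nm %in% names(de_tables)) stop("unknown DE table: ", nm)
      pick(de_tables[[nm]], rule)
    })
    combine <- if (is.null(rule$combine)) "union" else rule$combine
    out <- if (combine == "union") Reduce(union, sets)
           else Reduce(intersect, sets)
    if (!is.null(rule$intersect_with))
      out <- intersect(out, eval_rule(rule$intersect_with))
    sort(out)
  }
  lapply(rules, eval_rule)
}

#' n-tile integration of two per-gene measurements
#'
#' Genes are ranked by \code{values} (ties broken by gene id), split into n
#' bins whose sizes differ by at most 1 (bin 1 = lowest values), and the
#' paired \code{metric} is summarized per bin with a one-sample test
#' against zero.
#'
#' @param values Named numeric vector used for ranking (e.g. per-gene SON
#'   signal).
#' @param metric Named numeric vector summarized per bin (e.g. expression
#'   log2 fold change); names must match \code{values}.
#' @param n Number of bins (2 <= n <= number of genes).
#' @param test "wilcoxon" (signed-rank, default) or "ttest".
#' @return list with \code{bins} (per-gene data.frame: gene, value, metric,
#'   bin) and \code{summary} (per-bin: bin, n, median, iqr, p).
#' @export
ntile_integration <- function(values, metric, n = 10,
                              test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  genes <- intersect(names(values), names(metric))
  if (n < 2) stop("n must be >= 2")
  if (n > length(genes)) stop("more bins than genes")
  values <- values[genes]; metric <- metric[genes]
  ord <- order(values, genes)
  bin <- integer(length(genes))
  # bin sizes differ by <= 1: the first (length %% n) bins get the extra gene
  sizes <- rep(length(genes) %/% n, n)
  extra <- length(genes) %% n
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin[ord] <- rep(seq_len(n), times = sizes)
  summ <- lapply(seq_len(n), function(b) {
    m <- metric[bin == b]
    p <- if (all(m == 0)) 1
         else if (test == "wilcoxon")
           stats::wilcox.test(m, mu = 0, exact = FALSE)$p.value
         else stats::t.test(m, mu = 0)$p.value
    data.frame(bin = b, n = length(m), median = stats::median(m),
               iqr = stats::IQR(m), p = p)
  })
  list(bins = data.frame(gene = genes, value = unname(values),
                         metric = unname(metric), bin = bin,
                         stringsAsFactors = FALSE),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

#' Write domains or windows as BED
#'
#' BED5 with name = padj and score = -10 log10(padj) capped at 1000.
#'
#' @param domains Table with chrom, start, end, padj.
#' @param path Output path.
#' @export
write_domains_bed <- function(domains, path) {
  score <- pmin(round(-10 * log10(pmax(domains$padj, 1e-100))), 1000)
  utils::write.table(
    data.frame(domains$chrom, format(domains$start, scientific = FALSE),
               format(domains$end, scientific = FALSE),
               signif(domains$padj, 4), score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
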