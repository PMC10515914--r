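#' Speckle signature derivation and survival analysis
#'
#' The signature pipeline mirrors the multi-cohort workflow: per-cohort PCA
#' of speckle-resident-protein gene expression, sign anchoring on SON,
#' cross-cohort weight concordance, selection of consistently signed genes
#' into two reciprocal signatures, per-sample scoring, group assignment and
#' Kaplan-Meier / log-rank survival testing.
#'
#' @name speckle_signature
NULL

#' Upper-quartile normalize a count matrix
#'
#' Each sample (column) is scaled so the 75th percentile of its nonzero gene
#' values equals a fixed constant.
#'
#' @param counts Non-negative genes x samples matrix.
#' @param target Value the nonzero 75th percentile is scaled to.
#' @return Normalized matrix of the same shape.
#' @export
upper_quartile_normalize <- function(counts, target = 1000) {
  if (any(counts < 0)) stop("counts must be non-negative")
  uq <- apply(counts, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts")
    stats::quantile(nz, 0.75, names = FALSE)
  })
  sweep(counts, 2L, uq / target, "/")
}

#' Per-cohort PC1 weights of speckle genes, sign-anchored on SON
#'
#' Samples are observations and speckle genes variables; by default
#' expression is log2(x + 1)-transformed, then each gene is centered and
#' scaled to unit variance before PCA. The returned PC1 rotation is flipped,
#' if necessary, so the anchor gene's weight is <= 0. Zero-variance genes
#' are dropped with a warning.
#'
#' @param expr Genes x samples expression matrix for one cohort.
#' @param speckle_genes Genes to include (rows of \code{expr}).
#' @param anchor_gene Gene whose weight is forced non-positive.
#' @param log_transform log2(x + 1) before PCA (default TRUE).
#' @return list of class \code{cohort_weights}: \code{weights} (named,
#'   unit norm, anchor <= 0), \code{var_explained}, \code{dropped}.
#' @export
pc1_weights <- function(expr, speckle_genes, anchor_gene = "SON",
                        log_transform = TRUE) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  speckle_genes <- intersect(speckle_genes, rownames(expr))
  if (!anchor_gene %in% speckle_genes)
    stop("anchor gene ", anchor_gene, " absent from expression matrix")
  x <- t(expr[speckle_genes, , drop = FALSE])
  if (log_transform) x <- log2(x + 1)
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance genes: ",
            paste(dropped, collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (!anchor_gene %in% colnames(x))
      stop("anchor gene ", anchor_gene, " has zero variance")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  w <- p$rotation[, 1L]
  if (w[anchor_gene] > 0) w <- -w
  structure(list(weights = w,
                 var_explained = p$sdev[1L]^2 / sum(p$sdev^2),
                 dropped = dropped),
            class = "cohort_weights")
}

#' Pairwise Pearson concordance of cohort PC1 weights
#'
#' Weights are restricted to the genes shared by all cohorts (at least 3)
#' and compared as given, i.e. after sign anchoring.
#'
#' @param weights_list Named list of [pc1_weights()] results (or named
#'   numeric vectors).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
weight_concordance <- function(weights_list) {
  ws <- lapply(weights_list, function(w)
    if (inherits(w, "cohort_weights")) w$weights else w)
  shared <- Reduce(intersect, lapply(ws, names))
  if (length(shared) < 3) stop("fewer than 3 shared genes across cohorts")
  m <- vapply(ws, function(w) w[shared], numeric(length(shared)))
  stats::cor(m)
}

#' Select the concordant cohort block from a concordance matrix
#'
#' Cohorts are clustered by average linkage on 1 - r; the largest cluster
#' whose mean off-diagonal correlation is at least \code{min_mean_r} is
#' returned.
#'
#' @param concordance Correlation matrix from [weight_concordance()].
#' @param min_mean_r Minimum mean off-diagonal r within the block.
#' @return Character vector of cohort names.
#' @export
select_concordant_cohorts <- function(concordance, min_mean_r = 0.5) {
  if (nrow(concordance) < 2) return(rownames(concordance))
  hc <- stats::hclust(stats::as.dist(1 - concordance), method = "average")
  grp <- stats::cutree(hc, h = 1 - min_mean_r)
  best <- NULL
  for (g in unique(grp)) {
    mem <- names(grp)[grp == g]
    if (length(mem) < 2) next
    sub <- concordance[mem, mem]
    if (mean(sub[upper.tri(sub)]) < min_mean_r) next
    if (is.null(best) || length(mem) > length(best)) best <- mem
  }
  if (is.null(best)) stop("no cohort block reaches the concordance threshold")
  best
}

#' Select signature genes with consistently signed weights
#'
#' A gene is selected iff its anchored PC1 weight is strictly nonzero with
#' the same sign in every concordant cohort. Positive-sign genes become
#' Signature-I-high, negative-sign (anchor-like) genes Signature-II-high.
#' Genes missing from any cohort are excluded with a message.
#'
#' @param weights_list Named list of [pc1_weights()] results.
#' @param concordant_cohorts Cohorts to require consistency across.
#' @return data.frame of class \code{signature_gene_set}: \code{gene},
#'   \code{class} ("SigI-high"/"SigII-high").
#' @export
select_signature_genes <- function(weights_list, concordant_cohorts) {
  if (!length(concordant_cohorts)) stop("concordant cohort list is empty")
  ws <- lapply(weights_list[concordant_cohorts], function(w)
    if (inherits(w, "cohort_weights")) w$weights else w)
  all_genes <- unique(unlist(lapply(ws, names)))
  shared <- Reduce(intersect, lapply(ws, names))
  missing <- setdiff(all_genes, shared)
  if (length(missing))
    message("excluding genes missing from some cohort: ",
            paste(missing, collapse = ", "))
  m <- vapply(ws, function(w) w[shared], numeric(length(shared)))
  sig1 <- rowSums(m > 0) == ncol(m)
  sig2 <- rowSums(m < 0) == ncol(m)
  out <- data.frame(
    gene = c(shared[sig1], shared[sig2]),
    class = c(rep("SigI-high", sum(sig1)), rep("SigII-high", sum(sig2))),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_gene_set", "data.frame")
  out
}

#' Per-sample speckle score
#'
#' score = mean(z of Signature-I genes) - mean(z of Signature-II genes),
#' with per-gene z-scores computed across the reference sample set (the
#' scored samples themselves by default, in which case scores sum to zero).
#' Signature genes absent from the matrix are dropped with a warning and the
#' per-class counts adjusted.
#'
#' @param expr Genes x samples expression matrix for one cohort.
#' @param signature A [select_signature_genes()] data.frame.
#' @param z_reference Optional matrix from which per-gene mean/sd are fit
#'   (e.g. tumor samples when scoring normals); default: \code{expr} itself.
#' @param log_transform log2(x + 1) before z-scoring (default TRUE, matching
#'   [pc1_weights()]).
#' @return Named numeric vector of scores (one per sample).
#' @export
speckle_score <- function(expr, signature, z_reference = NULL,
                          log_transform = TRUE) {
  miss <- setdiff(signature$gene, rownames(expr))
  if (length(miss)) {
    warning("dropping signature genes missing from panel: ",
            paste(miss, collapse = ", "))
    signature <- signature[!signature$gene %in% miss, , drop = FALSE]
  }
  g1 <- signature$gene[signature$class == "SigI-high"]
  g2 <- signature$gene[signature$class == "SigII-high"]
  if (!length(g1) || !length(g2))
    stop("both signature classes must be non-empty after dropping")
  ref <- if (is.null(z_reference)) expr else z_reference
  tf <- function(m) if (log_transform) log2(m + 1) else m
  x <- tf(expr[signature$gene, , drop = FALSE])
  r <- tf(ref[signature$gene, , drop = FALSE])
  mu <- rowMeans(r)
  sd <- apply(r, 1L, stats::sd)
  sd[sd == 0] <- 1    # constant reference gene: z contributes 0
  z <- (x - mu) / sd
  colMeans(z[g1, , drop = FALSE]) - colMeans(z[g2, , drop = FALSE])
}

#' Assign samples to signature groups
#'
#' Quartile mode labels the top 25% of scores SignatureI and the bottom 25%
#' SignatureII (middle excluded); sign mode labels positive scores
#' SignatureI, negative SignatureII, exact zeros excluded. Quartile ties are
#' broken by stable sample order.
#'
#' @param scores Named numeric scores.
#' @param mode "quartile" or "sign".
#' @return Named character vector: "SignatureI", "SignatureII" or
#'   "excluded".
#' @export
assign_groups <- function(scores, mode = c("quartile", "sign")) {
  mode <- match.arg(mode)
  lab <- stats::setNames(rep("excluded", length(scores)), names(scores))
  if (mode == "sign") {
    lab[scores > 0] <- "SignatureI"
    lab[scores < 0] <- "SignatureII"
  } else {
    n <- length(scores)
    if (n < 4) stop("quartile mode needs at least 4 samples")
    k <- floor(n / 4)
    ord <- order(scores)   # stable: ties keep input order
    lab[ord[seq_len(k)]] <- "SignatureII"
    lab[ord[n - seq_len(k) + 1L]] <- "SignatureI"
  }
  lab
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator with right censoring; excluded samples are
#' ignored. With identical survival in both groups the statistic is 0 and
#' p = 1.
#'
#' @param labels Group labels ("excluded" entries dropped).
#' @param time,event Survival time and event indicator (1 = event).
#' @return list with \code{fit} ([survival::survfit] object), \code{chisq},
#'   \code{p}, \code{n_groups}.
#' @export
km_logrank <- function(labels, time, event) {
  keep <- labels != "excluded" & !is.na(labels)
  labels <- factor(labels[keep]); time <- time[keep]; event <- event[keep]
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("need two non-empty groups")
  s <- survival::Surv(time, event)
  fit <- survival::survfit(s ~ labels)
  sd <- survival::survdiff(s ~ labels)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = unname(p),
       n_groups = length(sd$n))
}

#' Per-gene expression bias between signature groups
#'
#' log2((mean_I + c) / (mean_II + c)) per gene plus a Wilcoxon rank-sum
#' p-value, as input for n-tile integration analyses.
#'
#' @param expr Genes x samples matrix.
#' @param labels Group labels as from [assign_groups()].
#' @param pseudocount Stabilizing constant c.
#' @return data.frame: gene, log2fc, p.
#' @export
group_expression_bias <- function(expr, labels, pseudocount = 1) {
  i1 <- names(labels)[labels == "SignatureI"]
  i2 <- names(labels)[labels == "SignatureII"]
  if (!length(i1) || !length(i2)) stop("both groups must be non-empty")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  p <- vapply(rownames(expr), function(g)
    stats::wilcox.test(expr[g, i1], expr[g, i2], exact = FALSE)$p.value,
    numeric(1))
  data.frame(gene = rownames(expr),
             log2fc = log2((m1 + pseudocount) / (m2 + pseudocount)),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Run the full signature pipeline on a multi-cohort panel
#'
#' Per-cohort anchored PC1 weights, cross-cohort concordance, concordant
#' block selection, signature gene selection, per-cohort scores, group
#' assignment and per-cohort log-rank tests.
#'
#' @param panel An \code{expression_panel} (see [gen_expression_panel()]) or
#'   a list with \code{expr}, \code{metadata}, \code{speckle_genes}.
#' @param anchor_gene Sign anchor, default "SON".
#' @param mode Grouping mode for survival ("quartile" or "sign").
#' @param min_mean_r Concordant-block threshold.
#' @param min_cohort_size Cohorts smaller than this are excluded.
#' @return list: \code{weights}, \code{concordance},
#'   \code{concordant_cohorts}, \code{signature}, \code{scores} (per
#'   cohort), \code{groups}, \code{survival} (per-cohort chisq and p).
#' @export
run_signature_pipeline <- function(panel, anchor_gene = "SON",
                                   mode = "quartile", min_mean_r = 0.5,
                                   min_cohort_size = 50) {
  md <- panel$metadata
  cohorts <- unique(md$cohort)
  cohorts <- cohorts[vapply(cohorts, function(co)
    sum(md$cohort == co) >= min_cohort_size, logical(1))]
  weights <- lapply(stats::setNames(cohorts, cohorts), function(co) {
    idx <- md$sample[md$cohort == co]
    pc1_weights(panel$expr[, idx, drop = FALSE], panel$speckle_genes,
                anchor_gene = anchor_gene)
  })
  conc <- weight_concordance(weights)
  concordant <- select_concordant_cohorts(conc, min_mean_r = min_mean_r)
  signature <- select_signature_genes(weights, concordant)
  scores <- lapply(stats::setNames(cohorts, cohorts), function(co) {
    idx <- md$sample[md$cohort == co]
    speckle_score(panel$expr[, idx, drop = FALSE], signature)
  })
  groups <- lapply(scores, assign_groups, mode = mode)
  surv <- lapply(stats::setNames(cohorts, cohorts), function(co) {
    g <- groups[[co]]
    sub <- md[match(names(g), md$sample), ]
    res <- tryCatch(km_logrank(g, sub$time_days, sub$event),
                    error = function(e) list(chisq = NA_real_, p = NA_real_))
    data.frame(cohort = co, chisq = res$chisq, p = res$p)
  })
  list(weights = weights, concordance = conc,
       concordant_cohorts = concordant, signature = signature,
       scores = scores, groups = groups,
       survival = do.call(rbind, c(surv, list(make.row.names = FALSE))))
}
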