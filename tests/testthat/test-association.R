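test_that("window counting formula and tiling hold", {
  w <- make_windows(c(chr1 = 1e6), 50000)
  expect_equal(nrow(w), 191)   # floor((1e6 - 5e4) / 5e3) + 1
  expect_equal(nrow(make_windows(c(chr1 = 49999), 50000)), 0)
  # each interior bp covered by exactly 10 windows on a toy chromosome
  w2 <- make_windows(c(chr1 = 200000), 50000)
  cover <- rep(0, 200000)
  for (i in seq_len(nrow(w2)))
    cover[(w2$start[i] + 1):w2$end[i]] <- cover[(w2$start[i] + 1):w2$end[i]] + 1
  interior <- (50000 + 1):(nrow(w2) * 5000)  # past the ramp-up, before ramp-down
  expect_true(all(cover[interior] == 10))
  # property: count formula vs brute force over random (L, size)
  set.seed(12)
  for (i in 1:20) {
    size <- sample(1:20, 1) * 10
    L <- sample(1:400, 1)
    n <- nrow(make_windows(c(c1 = L), size))
    brute <- sum(seq(0, max(L - size, 0), by = size / 10) + size <= L) *
      (L >= size)
    expect_equal(n, brute)
  }
  expect_error(make_windows(c(chr1 = 1e6), 33333), "divisible")
})

test_that("window quantification matches hand-computed cpm arithmetic", {
  # 3 hand-set bins fully inside one 300 bp window (step 30, bin 10)
  bins <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(10, 20, 30))
  w <- data.frame(chrom = "chr1", start = 0, end = 300, size = 300)
  cov <- matrix(c(10, 30, 60), ncol = 1)
  bg <- matrix(c(20, 20, 10), ncol = 1)
  sig <- quantify_windows(bins, cov, bg, w)
  cpm_cov <- c(10, 30, 60) / 100 * 1e6
  cpm_bg <- c(20, 20, 10) / 50 * 1e6
  expect_equal(sig[1, 1], sum(pmax(0, cpm_cov - cpm_bg)))
  # background == coverage -> all signal zero
  expect_equal(quantify_windows(bins, cov, cov, w)[1, 1], 0)
  # uniform coverage -> equal signal in all full windows
  bins2 <- data.frame(chrom = "chr1", start = seq(0, 190, 10),
                      end = seq(10, 200, 10))
  w2 <- make_windows(c(chr1 = 200), 100)
  cov2 <- matrix(rep(5, 20), ncol = 1)
  bg2 <- matrix(rep(1, 20), ncol = 1)
  s2 <- quantify_windows(bins2, cov2, bg2, w2)
  expect_equal(nrow(w2), 11)
  expect_true(all(abs(s2 - s2[1, 1]) < 1e-9))
  # misaligned grid is rejected
  wbad <- data.frame(chrom = "chr1", start = 0, end = 30, size = 30)
  expect_error(quantify_windows(bins, cov, bg, wbad), "align")
})

test_that("differential windows: degenerate equality and null calibration", {
  w <- data.frame(chrom = "chr1", start = seq(0, 90, 10),
                  end = seq(0, 90, 10) + 10, size = 10)[1:6, ]
  sig <- matrix(rep(c(5, 9, 14, 20, 7, 3), 4), ncol = 4)
  st <- differential_windows(w, sig, c("control", "control",
                                       "treatment", "treatment"))
  expect_equal(st$log2fc, rep(0, 6))
  expect_equal(st$p, rep(1, 6))
  expect_true(all(st$padj >= st$p - 1e-12))
  expect_error(differential_windows(w, sig[, c(1, 3)],
                                    c("control", "treatment")), "replicates")
})

test_that("null tracks produce at most 2% windows at padj < 0.01", {
  fracs <- vapply(1:20, function(s) {
    tr <- gen_track_truth(genome_length = 4e6, n_domains = 3,
                          domain_size = 6e5, n_depleted = 2, depletion = 1,
                          seed = s)
    tk <- gen_son_tracks(tr, seed = s)
    st <- run_assoc_pipeline(tk)
    mean(c(st[[1]]$padj, st[[2]]$padj) < 0.01)
  }, numeric(1))
  expect_lte(mean(fracs), 0.02)
  expect_lte(max(fracs), 0.05)
})

test_that("planted depletions are recovered as decreasing domains", {
  tr <- gen_track_truth(seed = 3)
  tk <- gen_son_tracks(tr, seed = 3)
  st <- run_assoc_pipeline(tk)
  # >= 90% of fully-inside 50 kb windows reach padj < 0.01
  s50 <- st[[1]]
  w50 <- make_windows(c(chr1 = tr$genome_length), 50000)
  dep <- tr$domains[tr$domains$depleted, ]
  inside_all <- rep(FALSE, nrow(w50))
  for (i in seq_len(nrow(dep)))
    inside_all <- inside_all | (w50$start >= dep$start[i] &
                                  w50$end <= dep$end[i])
  called <- s50$start[s50$padj < 0.01 & s50$direction == "decrease"]
  expect_gte(mean(w50$start[inside_all] %in% called), 0.9)
  # merged-domain Jaccard vs planted truth
  dom <- merge_domains(st[[1]], st[[2]])
  expect_gte(bp_jaccard(dom, dep, tr$genome_length), 0.8)
})

test_that("domain merging matches a brute-force interval-union oracle", {
  # book-ended and overlapping windows merge; disjoint stay apart
  mk <- function(start, end, padj, dir = "decrease")
    data.frame(chrom = "chr1", start = start, end = end, size = 50000,
               mean_signal = 1, log2fc = ifelse(dir == "decrease", -1, 1),
               t = 0, p = padj, padj = padj, direction = dir)
  st <- mk(c(0, 5000, 100000), c(50000, 55000, 150000), 1e-4)
  dom <- merge_domains(st, NULL)
  expect_equal(dom$start, c(0, 100000))
  expect_equal(dom$end, c(55000, 150000))
  expect_equal(dom$padj, c(1e-4, 1e-4))
  # merging is idempotent and order-independent
  dom_rev <- merge_domains(st[3:1, ], NULL)
  expect_equal(dom, dom_rev)
  # randomized toys vs oracle
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    starts <- sample(seq(0, 2e5, 5000), n, replace = TRUE)
    ends <- starts + sample(c(10000, 30000, 50000), n, replace = TRUE)
    st2 <- mk(starts, ends, runif(n, 0, 0.005))
    got <- merge_domains(st2, NULL)
    want <- oracle_interval_union(starts, ends, 3e5)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
  # threshold monotonicity: stricter threshold never grows the domain set
  st3 <- mk(c(0, 60000), c(50000, 110000), c(0.005, 0.05))
  expect_equal(nrow(merge_domains(st3, NULL, padj_threshold = 0.1)), 2)
  expect_equal(nrow(merge_domains(st3, NULL, padj_threshold = 0.01)), 1)
})

test_that("gene classification follows the printed padj thresholds", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10, 1010, 2010, 3010),
                      end = c(510, 1510, 2510, 3510),
                      gene_id = c("gA", "gB", "gC", "gD"))
  dom <- function(s, e, padj) data.frame(chrom = "chr1", start = s, end = e,
                                         padj = padj)
  tsa <- dom(c(0, 1000, 2000), c(600, 1600, 2600), c(0.005, 0.5, 0.05))
  cnr <- dom(c(0, 1000, 2000), c(600, 1600, 2600), c(0.3, 0.2, 0.5))
  cls <- classify_genes(tsa, cnr, genes)
  expect_equal(cls$class[cls$gene_id == "gA"], "associating")      # 0.005
  expect_equal(cls$class[cls$gene_id == "gB"], "non-associating")  # 0.5/0.2
  expect_equal(cls$class[cls$gene_id == "gC"], "ambiguous")        # 0.05/0.5
  expect_equal(cls$class[cls$gene_id == "gD"], "non-associating")  # no overlap
  # monotonicity: lowering the associating threshold never grows the set
  n_at <- function(th) sum(classify_genes(tsa, cnr, genes,
                                          assoc_padj = th)$class ==
                             "associating")
  expect_gte(n_at(0.06), n_at(0.01))
  expect_error(classify_genes(tsa, cnr, rbind(genes, genes)), "unique")
  bad <- genes; bad$end[1] <- bad$start[1]
  expect_error(classify_genes(tsa, cnr, bad), "malformed")
})

test_that("per-gene SON signal: hand arithmetic and domain separation", {
  bins <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30),
                     end = c(10, 20, 30, 40))
  cov <- matrix(c(10, 30, 50, 10), ncol = 1)
  bg <- matrix(c(10, 10, 10, 10), ncol = 1)
  genes <- data.frame(chrom = "chr1", start = c(10, 0), end = c(30, 40),
                      gene_id = c("g1", "g2"))
  v <- per_gene_son_signal(bins, cov, bg, genes)
  cpm_cov <- c(10, 30, 50, 10) / 100 * 1e6
  cpm_bg <- rep(250000, 4)
  expect_equal(unname(v["g1"]), mean(pmax(0, cpm_cov - cpm_bg)[2:3]))
  # uniform coverage, zero background -> identical values for all genes
  v2 <- per_gene_son_signal(bins, matrix(rep(5, 4)), matrix(rep(0, 4)), genes)
  expect_equal(unname(v2["g1"]), unname(v2["g2"]))
  # genes inside planted domains outscore genes outside (AUC)
  tr <- gen_track_truth(seed = 5)
  tk <- gen_son_tracks(tr, depth = 50, seed = 5)
  set.seed(5)
  gs <- data.frame(chrom = "chr1",
                   start = sort(sample(seq(0, tr$genome_length - 6e4, 1e4),
                                       120)))
  gs$end <- gs$start + 5e4
  gs$gene_id <- sprintf("G%03d", seq_len(nrow(gs)))
  inside <- rep(FALSE, nrow(gs))
  for (i in seq_len(nrow(tr$domains)))
    inside <- inside | (gs$start >= tr$domains$start[i] &
                          gs$end <= tr$domains$end[i])
  son <- per_gene_son_signal(tk$bins, tk$coverage$control,
                             tk$background$control, gs)
  auc <- mean(outer(son[inside], son[!inside], ">") +
                0.5 * outer(son[inside], son[!inside], "=="))
  expect_gte(auc, 0.95)
})

test_that("target gene sets reproduce hand-enumerated set algebra", {
  tabs <- list(
    h3 = data.frame(gene = c("A", "B", "C"), log2fc = c(-1, -2, 1),
                    p = c(0.01, 0.2, 0.01), padj = c(0.05, 0.4, 0.05)),
    h6 = data.frame(gene = c("A", "D"), log2fc = c(-1, -3),
                    p = c(0.5, 0.001), padj = c(0.9, 0.01)),
    tumor = data.frame(gene = c("A", "B", "D", "E"),
                       log2fc = c(0.5, 0.2, 1, 0.4),
                       p = c(0.01, 0.01, 0.3, 0.04),
                       padj = c(0.1, 0.1, 0.6, 0.2)))
  rules <- list(
    # decreasing at any timepoint: padj < 0.1 and log2fc < 0, union over tables
    decreasing = list(tables = c("h3", "h6"), padj_lt = 0.1, lfc_lt = 0,
                      combine = "union"),
    # the decreasing set additionally filtered by tumor-up (p<0.05, lfc>0.3)
    tumor_filtered = list(tables = c("h3", "h6"), padj_lt = 0.1, lfc_lt = 0,
                combine = "union",
                intersect_with = list(tables = "tumor", p_lt = 0.05,
                                      lfc_gt = 0.3)))
  sets <- define_target_gene_sets(tabs, rules)
  expect_setequal(sets$decreasing, c("A", "D"))   # A via h3; D via h6
  # tumor-up = {A, E} (B fails lfc, D fails p) -> intersection = {A}
  expect_setequal(sets$tumor_filtered, "A")
  empty <- define_target_gene_sets(
    list(t1 = data.frame(gene = character(0), log2fc = numeric(0),
                         p = numeric(0), padj = numeric(0))),
    list(s = list(tables = "t1", padj_lt = 0.1)))
  expect_equal(length(empty$s), 0)
  expect_error(define_target_gene_sets(
    list(t1 = data.frame(gene = "A")), list(s = list(tables = "t1",
                                                     padj_lt = 0.1))),
    "missing column")
})

test_that("n-tile integration bins correctly and detects planted monotonicity", {
  vals <- stats::setNames(1:100, sprintf("g%03d", 1:100))
  met0 <- stats::setNames(rep(0, 100), names(vals))
  nt <- ntile_integration(vals, met0, n = 10)
  expect_equal(as.integer(table(nt$bins$bin)), rep(10L, 10))
  expect_equal(nt$summary$median, rep(0, 10))
  # planted monotone relationship
  set.seed(9)
  met <- stats::setNames(as.numeric(vals) + rnorm(100, sd = 10), names(vals))
  nt2 <- ntile_integration(vals, met, n = 10)
  expect_gte(stats::cor(nt2$summary$bin, nt2$summary$median,
                        method = "spearman"), 0.9)
  expect_error(ntile_integration(vals[1:5], met0[1:5], n = 10), "more bins")
  # bin sizes differ by at most one when n does not divide the gene count
  nt3 <- ntile_integration(vals[1:97], met0[1:97], n = 10)
  expect_lte(diff(range(table(nt3$bins$bin))), 1)
})

test_that("integration links planted depletion to expression change", {
  # expression fold changes planted to depend on domain depletion
  tr <- gen_track_truth(seed = 13)
  tk <- gen_son_tracks(tr, seed = 13)
  st <- run_assoc_pipeline(tk)
  doms_loose <- lapply(st, function(s) s[s$direction == "decrease", ])
  set.seed(13)
  gs <- data.frame(chrom = "chr1",
                   start = seq(25000, tr$genome_length - 8e4, by = 60000))
  gs$end <- gs$start + 4e4
  gs$gene_id <- sprintf("G%03d", seq_len(nrow(gs)))
  dep <- tr$domains[tr$domains$depleted, ]
  in_dep <- rep(FALSE, nrow(gs))
  for (i in seq_len(nrow(dep)))
    in_dep <- in_dep | (gs$start < dep$end[i] & gs$end > dep$start[i])
  lfc <- stats::setNames(ifelse(in_dep, -1.5, 0) + rnorm(nrow(gs), sd = 0.3),
                         gs$gene_id)
  cls <- classify_genes(doms_loose[[1]], doms_loose[[2]], gs)
  assoc_genes <- cls$gene_id[cls$class == "associating"]
  expect_lt(stats::median(lfc[assoc_genes]), 0)
  # expression bias planted to follow speckle association: the top SON
  # decile (domain genes) departs from the bottom decile (background genes)
  son <- per_gene_son_signal(tk$bins, tk$coverage$control,
                             tk$background$control, gs)
  in_any <- rep(FALSE, nrow(gs))
  for (i in seq_len(nrow(tr$domains)))
    in_any <- in_any | (gs$start < tr$domains$end[i] &
                          gs$end > tr$domains$start[i])
  bias <- stats::setNames(0.8 * in_any + rnorm(nrow(gs), sd = 0.3),
                          gs$gene_id)
  nt <- ntile_integration(son, bias, n = 10)
  top <- nt$bins$metric[nt$bins$bin == 10]
  bottom <- nt$bins$metric[nt$bins$bin == 1]
  expect_lt(stats::wilcox.test(top, bottom)$p.value, 0.01)
})
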