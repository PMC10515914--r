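test_that("upper-quartile normalization: fixed point, scale invariance, hand case", {
  m <- matrix(c(1, 2, 3, 4, 0), ncol = 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  # hand arithmetic: nonzero values 1,2,3,4; type-7 75th percentile = 3.25
  norm <- upper_quartile_normalize(m, target = 1000)
  expect_equal(norm[, 1], m[, 1] / 3.25 * 1000)
  # doubling a sample changes nothing after normalization
  expect_equal(upper_quartile_normalize(2 * m), upper_quartile_normalize(m))
  # sample already at the target quantile is unchanged
  m2 <- m / 3.25 * 1000
  expect_equal(upper_quartile_normalize(m2, target = 1000), m2)
  expect_error(upper_quartile_normalize(matrix(0, 2, 1)), "all-zero")
})

test_that("pc1 weights: anchoring, symmetry, eigen oracle", {
  set.seed(2)
  # two perfectly anticorrelated blocks, no noise
  a <- rnorm(12)
  expr <- rbind(SON = -a, g2 = -a, g3 = a, g4 = a)
  colnames(expr) <- paste0("s", 1:12)
  w <- pc1_weights(2^expr - 0, rownames(expr), anchor_gene = "SON",
                   log_transform = FALSE)
  expect_lte(w$weights["SON"], 0)
  expect_equal(abs(unname(w$weights)), rep(0.5, 4), tolerance = 1e-8)
  expect_lt(max(w$weights[c("SON", "g2")]), 0)
  expect_gt(min(w$weights[c("g3", "g4")]), 0)

  # rotation matches an independent eigendecomposition of the correlation
  # matrix on a small random matrix
  x <- matrix(rexp(24), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  rownames(x)[1] <- "SON"
  w2 <- pc1_weights(x, rownames(x), log_transform = TRUE)
  ev <- eigen(stats::cor(t(log2(x + 1))))$vectors[, 1]
  names(ev) <- rownames(x)
  if (ev["SON"] > 0) ev <- -ev
  expect_equal(unname(w2$weights[names(ev)]), unname(ev), tolerance = 1e-8)

  # anchoring is idempotent: weights already anchored stay put
  expect_identical(w2$weights,
                   { v <- w2$weights; if (v["SON"] > 0) -v else v })
  expect_error(pc1_weights(x[, 1:2], rownames(x)), "3 samples")
  expect_error(pc1_weights(x, rownames(x), anchor_gene = "NOPE"), "anchor")
})

test_that("weight concordance resolves sign ambiguity via anchoring", {
  w <- c(SON = -0.5, a = 0.6, b = -0.4, c = 0.48)
  cc <- weight_concordance(list(c1 = w, c2 = w))
  expect_equal(unname(cc), matrix(1, 2, 2, dimnames = NULL))
  # a negated cohort re-anchors to +1 correlation
  w_neg <- -w
  if (w_neg["SON"] > 0) w_neg <- -w_neg
  cc2 <- weight_concordance(list(c1 = w, c2 = w_neg))
  expect_equal(cc2[1, 2], 1)
  expect_error(weight_concordance(list(c1 = w[1:2], c2 = w[3:4])), "shared")
})

test_that("signature gene selection applies the consistent-sign rule", {
  ws <- list(
    c1 = c(SON = -0.5, gA = 0.3, gB = 0.2, gC = -0.4),
    c2 = c(SON = -0.4, gA = 0.5, gB = -0.1, gC = -0.3),
    c3 = c(SON = -0.6, gA = 0.2, gB = 0.3, gC = -0.2))
  sig <- select_signature_genes(ws, c("c1", "c2", "c3"))
  expect_equal(sig$class[sig$gene == "gA"], "SigI-high")    # (+,+,+)
  expect_false("gB" %in% sig$gene)                           # (+,-,+)
  expect_equal(sig$class[sig$gene == "gC"], "SigII-high")   # (-,-,-)
  expect_equal(sig$class[sig$gene == "SON"], "SigII-high")
  expect_error(select_signature_genes(ws, character(0)), "empty")
})

test_that("speckle score follows the two-class z formula", {
  sig <- data.frame(gene = c("a1", "a2", "b1", "b2"),
                    class = c("SigI-high", "SigI-high",
                              "SigII-high", "SigII-high"))
  # craft expression whose z-scores are exactly +-1 for the target sample:
  # per-gene values (1, -1, 0) have mean 0 and sd 1
  expr <- rbind(a1 = c(1, -1, 0), a2 = c(1, -1, 0),
                b1 = c(-1, 1, 0), b2 = c(-1, 1, 0))
  colnames(expr) <- c("s1", "s2", "s3")
  sc <- speckle_score(expr, sig, log_transform = FALSE)
  # sample 1: all SigI genes at z = +1, all SigII at z = -1 -> score 2
  expect_equal(unname(sc["s1"]), 2)
  expect_equal(unname(sc["s2"]), -2)
  expect_equal(unname(sc["s3"]), 0)
  expect_equal(sum(sc), 0)
  # all-equal expression -> z = 0 -> score 0
  expr0 <- matrix(5, 4, 3, dimnames = list(sig$gene, paste0("s", 1:3)))
  expect_equal(unname(speckle_score(expr0, sig)), rep(0, 3))
  # swapping classes negates every score
  sig_sw <- sig; sig_sw$class <- rev(sig_sw$class)
  expect_equal(speckle_score(expr, sig_sw, log_transform = FALSE), -sc)
  # missing genes are dropped with a warning
  expect_warning(speckle_score(expr[1:3, ] + 2, sig), "dropping")
})

test_that("score is invariant to per-gene affine transforms of expression", {
  set.seed(8)
  sig <- data.frame(gene = paste0("g", 1:6),
                    class = rep(c("SigI-high", "SigII-high"), each = 3))
  expr <- matrix(rexp(60), 6, 10, dimnames = list(sig$gene, paste0("s", 1:10)))
  sc <- speckle_score(expr, sig, log_transform = FALSE)
  shifted <- expr * 3.7 + 11
  expect_equal(speckle_score(shifted, sig, log_transform = FALSE), sc,
               tolerance = 1e-10)
})

test_that("group assignment: quartile and sign semantics", {
  s <- stats::setNames(1:8, paste0("s", 1:8))
  g <- assign_groups(s, "quartile")
  expect_setequal(names(g)[g == "SignatureI"], c("s7", "s8"))
  expect_setequal(names(g)[g == "SignatureII"], c("s1", "s2"))
  expect_equal(sum(g == "excluded"), 4)
  g2 <- assign_groups(stats::setNames(c(0.5, -0.2, 0), c("a", "b", "c")),
                      "sign")
  expect_equal(unname(g2), c("SignatureI", "SignatureII", "excluded"))
  expect_error(assign_groups(s[1:3], "quartile"), "4 samples")
})

test_that("log-rank matches hand O-E/V arithmetic and degenerate cases", {
  # 6-subject worked table
  grp <- c("A", "A", "A", "B", "B", "B")
  tt <- c(1, 3, 5, 2, 4, 6); ev <- c(1, 1, 0, 1, 1, 1)
  res <- km_logrank(grp, tt, ev)
  expect_equal(res$chisq, oracle_logrank_chisq(grp, tt, ev), tolerance = 1e-10)
  # identical survival tables in both groups
  res0 <- km_logrank(rep(c("A", "B"), each = 4), rep(c(1, 2, 3, 4), 2),
                     rep(1, 8))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-10)
  # no censoring: KM equals the empirical survivor function
  fit <- km_logrank(grp, tt, rep(1, 6))$fit
  sA <- summary(fit)$surv[summary(fit)$strata == "labels=A"]
  expect_equal(sA, c(2/3, 1/3, 0))
  expect_error(km_logrank(c("A", "A"), c(1, 2), c(1, 1)), "two non-empty")
})

test_that("group expression bias: arithmetic and planted recovery", {
  labels <- stats::setNames(rep(c("SignatureI", "SignatureII"), each = 3),
                            paste0("s", 1:6))
  c0 <- 1
  expr <- rbind(flat = rep(2, 6), up = c(rep(3 * c0, 3), rep(c0, 3)))
  colnames(expr) <- names(labels)
  fc <- group_expression_bias(expr, labels, pseudocount = c0)
  expect_equal(fc$log2fc[fc$gene == "flat"], 0)
  expect_equal(fc$log2fc[fc$gene == "up"], 1)   # log2(4c/2c)
})

test_that("pipeline recovers planted signature and survival coupling", {
  panel <- gen_expression_panel(seed = 7)
  res <- run_signature_pipeline(panel)
  truth <- panel$truth

  # discordant cohorts are excluded from the concordant block
  expect_setequal(res$concordant_cohorts,
                  setdiff(sprintf("C%02d", 1:7), truth$discordant_cohorts))
  conc <- res$concordance[res$concordant_cohorts, res$concordant_cohorts]
  expect_gte(mean(conc[upper.tri(conc)]), 0.7)
  disc <- res$concordance[truth$discordant_cohorts, res$concordant_cohorts]
  expect_lt(mean(abs(disc)), 0.3)

  # gene classes recovered
  p1 <- names(truth$gene_class)[truth$gene_class == "SigI-planted"]
  p2 <- names(truth$gene_class)[truth$gene_class == "SigII-planted"]
  g1 <- res$signature$gene[res$signature$class == "SigI-high"]
  g2 <- res$signature$gene[res$signature$class == "SigII-high"]
  precision <- (sum(g1 %in% p1) + sum(g2 %in% p2)) / nrow(res$signature)
  recall <- (sum(p1 %in% g1) + sum(p2 %in% g2)) / (length(p1) + length(p2))
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)

  # score sign recovers the latent score sign; cohort scores sum to zero
  for (co in res$concordant_cohorts) {
    sc <- res$scores[[co]]
    expect_lt(abs(sum(sc)), 1e-9 * length(sc))
  }
  acc <- mean(sign(res$scores[["C01"]]) ==
                sign(truth$latent[names(res$scores[["C01"]])]))
  expect_gte(acc, 0.9)

  # quartile groups are enriched for extreme latent scores (rank-biserial)
  g <- res$groups[["C01"]]
  a <- truth$latent[names(g)]
  hi <- a[g == "SignatureI"]; lo <- a[g == "SignatureII"]
  rb <- 2 * (mean(outer(hi, lo, ">")) - 0.5)
  expect_gte(rb, 0.8)

  # survival flagged only in the coupled cohort
  sv <- res$survival
  expect_lt(sv$p[sv$cohort == truth$survival_cohort], 0.01)
  others <- sv$p[sv$cohort != truth$survival_cohort]
  expect_gt(stats::median(others), 0.1)

  # planted Signature-I genes show positive group fold changes
  md <- panel$metadata
  idx <- md$sample[md$cohort == "C01"]
  fc <- group_expression_bias(panel$expr[p1, idx, drop = FALSE],
                              res$groups[["C01"]])
  expect_gte(mean(fc$log2fc > 0), 0.9)
})
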