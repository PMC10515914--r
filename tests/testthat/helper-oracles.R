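# Independent oracles used across tests. These deliberately avoid the code
# paths they check: straight-line string counting for the STM criteria,
# exhaustive enumeration for local alignment, boolean-vector marking for
# interval unions, and textbook O-E/V arithmetic for the log-rank test.

# straight-line re-implementation of the five STM criteria on one 62-mer
oracle_stm_pass <- function(win) {
  stopifnot(nchar(win) == 62)
  cside <- strsplit(substr(win, 33, 62), "")[[1]]
  nside <- strsplit(substr(win, 1, 30), "")[[1]]
  all62 <- strsplit(win, "")[[1]]
  c1 <- !grepl("PPPPP", win, fixed = TRUE)
  c2 <- sum(all62[c(11, 16, 21, 26, 36, 41, 46) + 1] == "P") >= 3
  c3 <- sum(cside %in% c("T", "S", "E", "D")) >= 5
  c4 <- sum(nside %in% c("A", "M", "V", "F", "L", "I", "G")) >= 7
  c5 <- sum(all62 %in% c("R", "H", "K")) < 16
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, pass = c1 && c2 && c3 && c4 && c5)
}

# random 62-mer with a valid [TSED]P center
random_window <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  ch <- sample(aa, 62, replace = TRUE, prob = c(rep(1, 14), 3, rep(1, 5)))
  ch[31] <- sample(c("T", "S", "E", "D"), 1)
  ch[32] <- "P"
  paste(ch, collapse = "")
}

# exhaustive affine-gap local alignment score: maximize the global
# affine-gap score over all substring pairs (gap of length L costs
# open + L * extend, matching alignment_params())
oracle_local_score <- function(a, b, sm, open = 14, extend = 4) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  global_affine <- function(x, y) {
    nx <- length(x); ny <- length(y)
    rec2 <- function(i, j) {
      if (i == 0 && j == 0) return(0)
      best <- -Inf
      if (i > 0 && j > 0) best <- max(best, rec2(i - 1, j - 1) + sm[x[i], y[j]])
      if (i > 0) best <- max(best, gx(i - 1, j, 1))
      if (j > 0) best <- max(best, gy(i, j - 1, 1))
      best
    }
    gx <- function(i, j, len) {   # a gap in y consuming x down to i+1..
      best <- rec2(i, j) - open - extend * len
      if (i > 0) best <- max(best, gx(i - 1, j, len + 1))
      best
    }
    gy <- function(i, j, len) {
      best <- rec2(i, j) - open - extend * len
      if (j > 0) best <- max(best, gy(i, j - 1, len + 1))
      best
    }
    rec2(nx, ny)
  }
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b))
      best <- max(best, global_affine(a[i1:i2], b[j1:j2]))
  best
}

# brute-force union of half-open intervals via bp marking
oracle_interval_union <- function(starts, ends, upto) {
  v <- rep(FALSE, upto)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) v[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(v)
  pos <- cumsum(c(0, r$lengths))
  data.frame(start = pos[-length(pos)][r$values], end = pos[-1][r$values])
}

# textbook two-group log-rank chi-square (O-E)^2/V arithmetic
oracle_logrank_chisq <- function(group, time, event) {
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group == levels(factor(group))[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == levels(factor(group))[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# binary disk mask of radius R centered in a square image
disk_mask <- function(R, pad = 10) {
  sz <- 2 * R + 2 * pad + 1
  xg <- matrix(seq_len(sz), sz, sz); yg <- t(xg)
  c0 <- (sz + 1) / 2
  (xg - c0)^2 + (yg - c0)^2 <= R^2
}

# run the windowed differential pipeline on simulated tracks for one or
# both window sizes
run_assoc_pipeline <- function(tracks, sizes = c(50000, 100000)) {
  truth <- tracks$truth
  lapply(sizes, function(sz) {
    w <- make_windows(c(chr1 = truth$genome_length), sz)
    sig <- cbind(
      quantify_windows(tracks$bins, tracks$coverage$control,
                       tracks$background$control, w),
      quantify_windows(tracks$bins, tracks$coverage$treatment,
                       tracks$background$treatment, w))
    differential_windows(w, sig, rep(c("control", "treatment"),
                                     each = ncol(tracks$coverage$control)))
  })
}

# base-pair Jaccard between two half-open interval tables
bp_jaccard <- function(a, b, genome_length, res = 1000) {
  mark <- function(d) {
    v <- rep(FALSE, genome_length / res)
    for (i in seq_len(nrow(d)))
      v[(d$start[i] / res + 1):(d$end[i] / res)] <- TRUE
    v
  }
  va <- mark(a); vb <- mark(b)
  sum(va & vb) / sum(va | vb)
}
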