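#' Synthetic data generators with planted ground truth
#'
#' Every downstream stage of the package (signature derivation, STM
#' scanning, differential speckle-association calling, radial imaging) has a
#' matching generator here that plants a known truth, so parameter-recovery
#' tests need no external downloads. Identical parameters and seed yield
#' identical outputs.
#'
#' @name synthetic_data
NULL

# approximate human proteome amino-acid frequencies (percent); fixed, not
# configurable, for test stability
.AA_FREQ <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
              G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
              P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)

.sample_aa <- function(n, exclude = NULL) {
  f <- .AA_FREQ
  if (length(exclude)) f <- f[setdiff(names(f), exclude)]
  sample(names(f), n, replace = TRUE, prob = f)
}

## ---------------------------------------------------------------- expression

#' Generate a multi-cohort expression panel with planted speckle signature
#'
#' Plants two reciprocally expressed speckle-gene blocks: each sample s has a
#' latent score a_s ~ N(0, 1) per cohort, and log2 expression is
#' mu_g + w_g * beta_expr * a_s + eps with w_g = +1 for Signature-I-planted
#' genes, -1 for Signature-II-planted genes (the anchor gene SON is planted
#' in the Signature-II block) and 0 otherwise. In discordant cohorts w_g is
#' randomly re-signed per gene, destroying cross-cohort weight concordance.
#' Survival times are exponential with hazard proportional to
#' exp(beta_haz * a_s) in the designated cohort and independent of a_s in all
#' others; censoring is administrative uniform.
#'
#' @param n_cohorts Number of cohorts (the last `n_discordant_cohorts` are
#'   discordant).
#' @param samples_per_cohort Samples per cohort.
#' @param n_speckle_genes Total designated speckle genes (>= n_sig1 + n_sig2;
#'   the remainder carry no signal).
#' @param n_sig1,n_sig2 Planted Signature-I / Signature-II gene counts.
#' @param n_background Non-speckle background genes.
#' @param n_discordant_cohorts Cohorts with per-gene re-signed weights.
#' @param beta_expr Expression shift (log2 units) per unit latent score.
#' @param noise_sd Residual log2 noise sd (>= 0).
#' @param beta_haz Hazard coefficient in the survival-coupled cohort.
#' @param baseline_hazard Baseline exponential hazard (per day).
#' @param censor_frac Expected censored fraction in [0, 1).
#' @param survival_cohort Index of the survival-coupled cohort.
#' @param seed Integer seed; identical seed implies identical output.
#' @return list of class \code{expression_panel}: \code{expr} (genes x
#'   samples, non-negative), \code{metadata} (sample, cohort, tumor_normal,
#'   stage, time_days, event), \code{speckle_genes}, and \code{truth}
#'   (per-gene class, per-sample latent score, cohort roles).
#' @export
gen_expression_panel <- function(n_cohorts = 7, samples_per_cohort = 100,
                                 n_speckle_genes = 60, n_sig1 = 20,
                                 n_sig2 = 30, n_background = 140,
                                 n_discordant_cohorts = 2, beta_expr = 2,
                                 noise_sd = 1, beta_haz = 1,
                                 baseline_hazard = 5e-4, censor_frac = 0.3,
                                 survival_cohort = 1, seed = 1) {
  if (n_cohorts < 1 || samples_per_cohort < 1 || n_speckle_genes < 1)
    stop("dimensions must be positive")
  if (n_sig1 + n_sig2 > n_speckle_genes)
    stop("n_sig1 + n_sig2 must not exceed n_speckle_genes")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_discordant_cohorts >= n_cohorts)
    stop("need at least one concordant cohort")
  set.seed(seed)

  speckle_genes <- c("SON",
                     sprintf("SPK%03d", seq_len(n_speckle_genes - 1L)))
  bg_genes <- if (n_background > 0) sprintf("BGD%03d", seq_len(n_background))
              else character(0)
  genes <- c(speckle_genes, bg_genes)
  # SON is the first Signature-II-planted gene (weight -1)
  sig2 <- c("SON", speckle_genes[1L + seq_len(n_sig2 - 1L)])
  sig1 <- speckle_genes[n_sig2 + seq_len(n_sig1)]
  w <- stats::setNames(numeric(length(genes)), genes)
  w[sig1] <- 1; w[sig2] <- -1
  gene_class <- stats::setNames(rep("background", length(genes)), genes)
  gene_class[sig1] <- "SigI-planted"; gene_class[sig2] <- "SigII-planted"

  mu <- stats::setNames(stats::runif(length(genes), 3, 8), genes)
  cohorts <- sprintf("C%02d", seq_len(n_cohorts))
  discordant <- if (n_discordant_cohorts > 0)
    cohorts[n_cohorts - seq_len(n_discordant_cohorts) + 1L] else character(0)

  expr_list <- list(); meta_list <- list(); a_all <- numeric(0)
  for (ci in seq_len(n_cohorts)) {
    co <- cohorts[ci]
    a <- stats::rnorm(samples_per_cohort)
    ids <- sprintf("%s_S%03d", co, seq_len(samples_per_cohort))
    names(a) <- ids
    w_eff <- w
    if (co %in% discordant) {
      flip <- sample(c(-1, 1), length(genes), replace = TRUE)
      w_eff <- w * flip
    }
    logx <- outer(mu, rep(1, samples_per_cohort)) +
      outer(w_eff * beta_expr, a) +
      matrix(stats::rnorm(length(genes) * samples_per_cohort, sd = noise_sd),
             nrow = length(genes))
    x <- 2^logx
    colnames(x) <- ids; rownames(x) <- genes
    surv_scores <- if (ci == survival_cohort) a else rep(0, length(a))
    surv <- gen_survival_from_scores(surv_scores, beta_haz = beta_haz,
                                     baseline_hazard = baseline_hazard,
                                     censor_frac = censor_frac, seed = NULL)
    meta_list[[co]] <- data.frame(
      sample = ids, cohort = co, tumor_normal = "tumor",
      stage = sample(c("I", "II", "III", "IV"), samples_per_cohort,
                     replace = TRUE),
      time_days = surv$time, event = surv$event, stringsAsFactors = FALSE)
    expr_list[[co]] <- x
    a_all <- c(a_all, a)
  }
  structure(list(
    expr = do.call(cbind, expr_list),
    metadata = do.call(rbind, c(meta_list, list(make.row.names = FALSE))),
    speckle_genes = speckle_genes,
    truth = list(gene_class = gene_class, weights = w, latent = a_all,
                 survival_cohort = cohorts[survival_cohort],
                 discordant_cohorts = discordant,
                 beta_expr = beta_expr, beta_haz = beta_haz)),
    class = "expression_panel")
}

#' Generate survival times coupled to a score
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * exp(beta_haz * score)}; censoring is
#' administrative uniform on [0, T_max], independent of the score, with
#' T_max solved numerically so the expected censored fraction equals
#' \code{censor_frac}.
#'
#' @param scores Numeric scores (one per subject).
#' @param beta_haz Log-hazard ratio per unit score.
#' @param baseline_hazard Positive baseline hazard.
#' @param censor_frac Expected censored fraction in [0, 1); 0 disables
#'   censoring.
#' @param seed Optional integer seed (NULL continues the current RNG stream).
#' @return data.frame with \code{time} and \code{event} (1 = event observed).
#' @export
gen_survival_from_scores <- function(scores, beta_haz = 1,
                                     baseline_hazard = 5e-4,
                                     censor_frac = 0.3, seed = NULL) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must be in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  rate <- baseline_hazard * exp(beta_haz * scores)
  tt <- stats::rexp(length(scores), rate)
  if (censor_frac == 0)
    return(data.frame(time = tt, event = rep(1L, length(tt))))
  frac_censored <- function(tmax) mean((1 - exp(-rate * tmax)) / (rate * tmax))
  hi <- 1 / baseline_hazard
  while (frac_censored(hi) > censor_frac) hi <- hi * 2
  tmax <- stats::uniroot(function(x) frac_censored(x) - censor_frac,
                         lower = 1e-9 / baseline_hazard, upper = hi)$root
  cc <- stats::runif(length(scores), 0, tmax)
  data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
}

## ------------------------------------------------------------------ proteome

# build one random 62-mer guaranteed to pass all five STM criteria; the
# forced positions are chosen so that each decoy mutation below can break
# exactly one criterion
.make_stm_window <- function() {
  repeat {
    win <- .sample_aa(62)
    win[c(12, 17, 22, 27)] <- "P"                  # N-side spaced prolines
    win[31] <- sample(c("T", "S", "E", "D"), 1L)
    win[32] <- "P"
    # >= 10 hydrophobic/small on the N side, away from idx 0..4 (so a decoy
    # proline run there cannot starve criterion 4) and off the spaced slots
    nfree <- setdiff(6:30, c(12, 17, 22, 27))
    hyd <- sample(nfree, 10)
    win[hyd] <- sample(c("A", "M", "V", "F", "L", "I", "G"), 10, replace = TRUE)
    # >= 8 T/S/E/D on the C side, off the spaced slots
    cfree <- setdiff(33:62, c(37, 42, 47))
    acid <- sample(cfree, 8)
    win[acid] <- sample(c("T", "S", "E", "D"), 8, replace = TRUE)
    chk <- apply_stm_criteria(paste(win, collapse = ""))
    if (chk$pass) return(list(win = win, hyd = hyd, acid = acid))
  }
}

# mutate a passing window so that exactly criterion k fails
.make_decoy_window <- function(k) {
  repeat {
    base <- .make_stm_window()
    win <- base$win
    if (k == 1L) {
      win[1:5] <- "P"
      if (win[6] == "P") win[6] <- "A"   # cap the run at exactly 5
    } else if (k == 2L) {
      win[c(12, 17, 22, 27)] <- sample(c("A", "L", "G"), 4, replace = TRUE)
      win[c(37, 42, 47)][win[c(37, 42, 47)] == "P"] <- "A"
    } else if (k == 3L) {
      cside <- 33:62
      win[cside][win[cside] %in% c("T", "S", "E", "D")] <- "A"
    } else if (k == 4L) {
      nside <- 1:30
      hydro <- c("A", "M", "V", "F", "L", "I", "G")
      win[nside][win[nside] %in% hydro] <- "S"
    } else if (k == 5L) {
      free <- setdiff(seq_len(62),
                      c(12, 17, 22, 27, 31, 32, base$hyd, base$acid))
      win[sample(free, 16)] <- "K"
    } else stop("criterion index must be 1..5")
    chk <- apply_stm_criteria(paste(win, collapse = ""))
    crit <- unlist(chk[c("c1", "c2", "c3", "c4", "c5")])
    if (!crit[k] && all(crit[-k])) return(win)
  }
}

# random background protein with no passing STM window
.make_clean_protein <- function(len) {
  repeat {
    s <- paste(.sample_aa(len), collapse = "")
    cand <- extract_candidate_windows(s)
    if (nrow(cand) == 0L || !any(apply_stm_criteria(cand)$pass)) return(s)
  }
}

# insert a 62-mer into background sequence; reject if any passing window
# other than ones overlapping the insert appears (background), or if any
# passing window at all appears (want_pass = FALSE)
.plant_window <- function(win, len, want_pass) {
  repeat {
    off <- sample.int(len - 62L + 1L, 1L) - 1L    # 0-based insert offset
    s <- .sample_aa(len)
    s[off + seq_len(62L)] <- win
    s <- paste(s, collapse = "")
    cand <- extract_candidate_windows(s)
    scored <- if (nrow(cand)) apply_stm_criteria(cand) else cand
    hits <- if (nrow(cand)) scored$window_start[scored$pass] else integer(0)
    overlaps_insert <- hits < off + 62L & hits + 62L > off
    if (want_pass) {
      if (off %in% hits && all(overlaps_insert)) return(list(seq = s, off = off))
    } else {
      if (!length(hits)) return(list(seq = s, off = off))
    }
  }
}

#' Generate a synthetic proteome with planted STMs and decoys
#'
#' Background proteins are drawn from a fixed human-like amino-acid
#' frequency table and contain no passing STM window; planted proteins
#' contain a window satisfying all five criteria by construction; decoys
#' contain a window failing exactly its designated criterion (and no passing
#' window anywhere).
#'
#' @param n_background,n_planted Number of background / STM-planted proteins.
#' @param n_decoys_per_criterion Decoy proteins per criterion (5 criteria).
#' @param length_range Protein length range (min >= 62 when windows are
#'   planted).
#' @param seed Integer seed.
#' @return list with \code{proteome} ([Biostrings::AAStringSet]) and
#'   \code{truth} (data.frame: protein_id, label, stm_start (0-based),
#'   criterion).
#' @export
gen_proteome <- function(n_background = 30, n_planted = 10,
                         n_decoys_per_criterion = 2,
                         length_range = c(200, 400), seed = 1) {
  if ((n_planted > 0 || n_decoys_per_criterion > 0) && length_range[1] < 62)
    stop("planted/decoy proteins require length >= 62")
  set.seed(seed)
  ids <- character(0); seqs <- character(0)
  truth <- data.frame(protein_id = character(0), label = character(0),
                      stm_start = integer(0), criterion = integer(0),
                      stringsAsFactors = FALSE)
  rlen <- function()
    length_range[1] + sample.int(length_range[2] - length_range[1] + 1L, 1L) - 1L
  for (i in seq_len(n_planted)) {
    p <- .plant_window(.make_stm_window()$win, rlen(), want_pass = TRUE)
    id <- sprintf("STM%03d", i)
    ids <- c(ids, id); seqs <- c(seqs, p$seq)
    truth <- rbind(truth, data.frame(protein_id = id, label = "STM-planted",
                                     stm_start = p$off, criterion = NA_integer_))
  }
  for (k in seq_len(5)) for (j in seq_len(n_decoys_per_criterion)) {
    p <- .plant_window(.make_decoy_window(k), rlen(), want_pass = FALSE)
    id <- sprintf("DEC%d_%02d", k, j)
    ids <- c(ids, id); seqs <- c(seqs, p$seq)
    truth <- rbind(truth, data.frame(
      protein_id = id, label = sprintf("decoy-violating-criterion-%d", k),
      stm_start = p$off, criterion = k))
  }
  for (i in seq_len(n_background)) {
    id <- sprintf("BGP%03d", i)
    ids <- c(ids, id); seqs <- c(seqs, .make_clean_protein(rlen()))
    truth <- rbind(truth, data.frame(protein_id = id, label = "background",
                                     stm_start = NA_integer_,
                                     criterion = NA_integer_))
  }
  proteome <- Biostrings::AAStringSet(seqs)
  names(proteome) <- ids
  rownames(truth) <- NULL
  list(proteome = proteome, truth = truth)
}

## ----------------------------------------------------------------- SON tracks

#' Plant SON domain structure for coverage simulation
#'
#' Domains are non-overlapping, sorted, bin-aligned elevated-rate intervals;
#' a subset is flagged depleted-in-treatment with a common depletion factor
#' d in (0, 1).
#'
#' @param genome_length Genome (single chromosome) length in bp.
#' @param bin_size Coverage bin width in bp (must divide genome_length).
#' @param n_domains Number of elevated SON domains.
#' @param domain_size Domain width in bp (bin multiple).
#' @param n_depleted Number of domains depleted in the treatment condition.
#' @param depletion Depletion factor d in (0, 1); 1 means no depletion.
#' @param multiplier Rate multiplier of domains over background.
#' @param background_rate Uniform background rate per bin (arbitrary units).
#' @param seed Integer seed.
#' @return list of class \code{track_truth}.
#' @export
gen_track_truth <- function(genome_length = 1.2e7, bin_size = 5000,
                            n_domains = 6, domain_size = 1e6, n_depleted = 3,
                            depletion = 0.4, multiplier = 5,
                            background_rate = 1, seed = 1) {
  if (depletion <= 0 || depletion > 1) stop("depletion must be in (0, 1]")
  if (genome_length %% bin_size != 0) stop("bin_size must divide genome_length")
  set.seed(seed)
  slot <- (genome_length %/% n_domains) %/% bin_size * bin_size
  if (domain_size >= slot) stop("domains do not fit the genome")
  starts <- vapply(seq_len(n_domains) - 1L, function(i) {
    room <- (slot - domain_size) %/% bin_size
    i * slot + bin_size * sample.int(room, 1L)
  }, numeric(1))
  depleted <- sort(sample.int(n_domains, n_depleted))
  domains <- data.frame(start = starts, end = starts + domain_size,
                        multiplier = multiplier,
                        depleted = seq_len(n_domains) %in% depleted)
  stopifnot(all(diff(domains$start) > 0),
            all(domains$start[-1] >= domains$end[-n_domains]))
  structure(list(domains = domains, depletion = depletion,
                 background_rate = background_rate, bin_size = bin_size,
                 genome_length = genome_length), class = "track_truth")
}

#' Simulate binned SON coverage for two conditions plus background tracks
#'
#' Per-bin counts are Poisson (negative binomial when a finite dispersion
#' size is given) with rate depth * background_rate outside domains and
#' depth * background_rate * multiplier inside, multiplied by the depletion
#' factor d for depleted domains in the treatment condition. Background
#' (input/IgG) tracks are uniform Poisson at the background rate.
#'
#' @param truth A [gen_track_truth()] object.
#' @param n_replicates Replicates per condition (>= 2 for testing).
#' @param depth Positive sequencing-depth scale factor.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial size; Inf (default) gives Poisson.
#' @return list of class \code{son_tracks}: \code{bins} (chrom/start/end),
#'   per-condition count matrices \code{coverage$control},
#'   \code{coverage$treatment} (bins x replicates) and matching
#'   \code{background} matrices.
#' @export
gen_son_tracks <- function(truth, n_replicates = 2, depth = 20, seed = 1,
                           dispersion = Inf) {
  if (depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  nb <- truth$genome_length %/% truth$bin_size
  starts <- (seq_len(nb) - 1L) * truth$bin_size
  rate0 <- rep(truth$background_rate, nb)
  rate_ctrl <- rate0; rate_trt <- rate0
  for (i in seq_len(nrow(truth$domains))) {
    d <- truth$domains[i, ]
    idx <- which(starts >= d$start & starts < d$end)
    rate_ctrl[idx] <- truth$background_rate * d$multiplier
    rate_trt[idx] <- truth$background_rate * d$multiplier *
      if (d$depleted) truth$depletion else 1
  }
  draw <- function(rate) {
    mu <- depth * rate
    cnt <- if (is.finite(dispersion))
      stats::rnbinom(length(mu) * n_replicates, mu = rep(mu, n_replicates),
                     size = dispersion)
    else stats::rpois(length(mu) * n_replicates, rep(mu, n_replicates))
    matrix(cnt, nrow = length(mu), ncol = n_replicates,
           dimnames = list(NULL, sprintf("rep%d", seq_len(n_replicates))))
  }
  structure(list(
    bins = data.frame(chrom = "chr1", start = starts,
                      end = starts + truth$bin_size),
    coverage = list(control = draw(rate_ctrl), treatment = draw(rate_trt)),
    background = list(control = draw(rate0), treatment = draw(rate0)),
    truth = truth), class = "son_tracks")
}

## -------------------------------------------------------------------- images

#' Simulate DAPI/SON nucleus images with controllable speckle radial bias
#'
#' Nuclei are non-overlapping ellipses placed by rejection sampling; the SON
#' channel is a sum of Gaussian speckle spots plus Gaussian noise, the DAPI
#' channel a smooth filled ellipse per nucleus. Speckle centers are drawn at
#' normalized elliptical radius r = 0.92 * U^((1 + b) / 2) (U uniform): at
#' radial bias b = 0 the placement is area-uniform, larger b concentrates
#' speckles toward the nucleus center. All speckle centers lie inside their
#' nucleus mask.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param image_size Square image side in pixels.
#' @param radius_range Semi-major axis range (px).
#' @param axis_ratio_range Semi-minor / semi-major ratio range.
#' @param n_speckles Speckle spots per nucleus.
#' @param bias Radial bias b >= 0 (0 = uniform, larger = more central).
#' @param spot_amplitude,spot_sd Gaussian spot peak height and width (px).
#' @param noise_sd Additive Gaussian noise sd on the SON channel.
#' @param dapi_level DAPI fill intensity.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget; exceeding it errors (nuclei
#'   would overlap beyond tolerance).
#' @return list of class \code{nuclei_images}: \code{dapi}, \code{son}
#'   (numeric matrices), \code{truth} (per-nucleus ellipse parameters and
#'   per-speckle centers).
#' @export
gen_nuclei_images <- function(n_nuclei = 20, image_size = 256,
                              radius_range = c(12, 18),
                              axis_ratio_range = c(0.75, 1),
                              n_speckles = 8, bias = 0, spot_amplitude = 50,
                              spot_sd = 1.6, noise_sd = 1, dapi_level = 100,
                              seed = 1, max_tries = 5000) {
  if (bias < 0) stop("bias must be >= 0")
  set.seed(seed)
  margin <- radius_range[2] + 3
  if (2 * margin >= image_size) stop("nuclei do not fit inside image bounds")
  nuc <- data.frame()
  tries <- 0
  while (nrow(nuc) < n_nuclei) {
    tries <- tries + 1
    if (tries > max_tries) stop("could not place non-overlapping nuclei")
    a <- stats::runif(1, radius_range[1], radius_range[2])
    b <- a * stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
    th <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, margin, image_size - margin)
    cy <- stats::runif(1, margin, image_size - margin)
    if (nrow(nuc) == 0 ||
        all(sqrt((nuc$cx - cx)^2 + (nuc$cy - cy)^2) > nuc$a + a + 2))
      nuc <- rbind(nuc, data.frame(id = nrow(nuc) + 1L, cx = cx, cy = cy,
                                   a = a, b = b, theta = th))
  }
  dapi <- matrix(0, image_size, image_size)
  son <- matrix(0, image_size, image_size)
  xg <- matrix(seq_len(image_size), image_size, image_size)
  yg <- t(xg)
  spots <- data.frame()
  for (i in seq_len(nrow(nuc))) {
    p <- nuc[i, ]
    dx <- xg - p$cx; dy <- yg - p$cy
    u <- dx * cos(p$theta) + dy * sin(p$theta)
    v <- -dx * sin(p$theta) + dy * cos(p$theta)
    inside <- (u / p$a)^2 + (v / p$b)^2 <= 1
    dapi[inside] <- dapi_level
    for (k in seq_len(n_speckles)) {
      r <- 0.92 * stats::runif(1)^((1 + bias) / 2)
      phi <- stats::runif(1, 0, 2 * pi)
      su <- r * p$a * cos(phi); sv <- r * p$b * sin(phi)
      sx <- p$cx + su * cos(p$theta) - sv * sin(p$theta)
      sy <- p$cy + su * sin(p$theta) + sv * cos(p$theta)
      spots <- rbind(spots, data.frame(nucleus = p$id, x = sx, y = sy, r = r))
      d2 <- (xg - sx)^2 + (yg - sy)^2
      near <- d2 < (6 * spot_sd)^2
      son[near] <- son[near] +
        spot_amplitude * exp(-d2[near] / (2 * spot_sd^2))
    }
  }
  dapi <- as.matrix(EBImage::gblur(EBImage::Image(dapi / max(dapi)),
                                   sigma = 1)) * dapi_level
  if (noise_sd > 0)
    son <- son + matrix(stats::rnorm(length(son), sd = noise_sd),
                        nrow = nrow(son))
  son[son < 0] <- 0
  structure(list(dapi = dapi, son = son,
                 truth = list(nuclei = nuc, speckles = spots, bias = bias)),
            class = "nuclei_images")
}

#' Simulate an imaging cohort with per-sample radial bias
#'
#' One image per sample, with the sample's speckle radial-bias parameter
#' drawn uniformly from \code{bias_range}. Returns the generated images'
#' per-sample truth; pair with [gen_survival_from_scores()] on the
#' standardized bias to couple survival to the planted central fraction.
#'
#' @param n_samples Number of samples (images).
#' @param nuclei_per_sample Nuclei per image.
#' @param image_size Image side (px).
#' @param bias_range Range the per-sample radial bias is drawn from.
#' @param n_speckles,noise_sd Passed to [gen_nuclei_images()].
#' @param seed Integer seed.
#' @return list: \code{images} (list of \code{nuclei_images}),
#'   \code{samples} (data.frame: sample, bias, central_fraction — the
#'   planted per-sample fraction of speckle centers in the most central
#'   quarter of normalized radius, the quantity survival should couple to).
#' @export
gen_imaging_cohort <- function(n_samples = 80, nuclei_per_sample = 12,
                               image_size = 240, bias_range = c(0, 2),
                               n_speckles = 6, noise_sd = 1, seed = 1) {
  set.seed(seed)
  bias <- stats::runif(n_samples, bias_range[1], bias_range[2])
  sub_seeds <- sample.int(.Machine$integer.max, n_samples)
  ids <- sprintf("S%03d", seq_len(n_samples))
  images <- lapply(seq_len(n_samples), function(i)
    gen_nuclei_images(n_nuclei = nuclei_per_sample, image_size = image_size,
                      n_speckles = n_speckles, bias = bias[i],
                      noise_sd = noise_sd, seed = sub_seeds[i]))
  names(images) <- ids
  central <- vapply(images, function(im)
    mean(im$truth$speckles$r < 0.25), numeric(1))
  list(images = images,
       samples = data.frame(sample = ids, bias = bias,
                            central_fraction = unname(central),
                            stringsAsFactors = FALSE))
}

## ----------------------------------------------------------------- writers

#' Write synthetic outputs in standard interchange formats
#'
#' Writers for the generator outputs: FASTA (proteome), TSV (expression and
#' survival), bedGraph (binned coverage), BED (true domains), 16-bit TIFF
#' (images) and a JSON truth sidecar. All outputs round-trip through the
#' package readers.
#'
#' @param x Generator output object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @name synthetic_writers
NULL

#' @rdname synthetic_writers
#' @export
write_proteome <- function(x, dir, prefix = "proteome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  Biostrings::writeXStringSet(x$proteome, fa)
  tr <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(x$truth, tr, dataframe = "columns", na = "null")
  invisible(c(fa, tr))
}

#' @rdname synthetic_writers
#' @export
write_expression_panel <- function(x, dir, prefix = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ef <- file.path(dir, paste0(prefix, "_expr.tsv"))
  utils::write.table(data.frame(gene = rownames(x$expr), x$expr,
                                check.names = FALSE),
                     ef, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  utils::write.table(x$metadata, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ef, mf))
}

#' @rdname synthetic_writers
#' @export
write_son_tracks <- function(x, dir, prefix = "son") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wbg <- function(counts, name) {
    f <- file.path(dir, paste0(prefix, "_", name, ".bedGraph"))
    utils::write.table(cbind(x$bins, counts), f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    f
  }
  for (cond in names(x$coverage))
    for (r in seq_len(ncol(x$coverage[[cond]]))) {
      paths <- c(paths, wbg(x$coverage[[cond]][, r],
                            sprintf("%s_rep%d", cond, r)))
      paths <- c(paths, wbg(x$background[[cond]][, r],
                            sprintf("%s_rep%d_background", cond, r)))
    }
  bed <- file.path(dir, paste0(prefix, "_true_domains.bed"))
  d <- x$truth$domains
  utils::write.table(data.frame("chr1", format(d$start, scientific = FALSE),
                                format(d$end, scientific = FALSE),
                                ifelse(d$depleted, "depleted", "stable")),
                     bed, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(paths, bed))
}

#' @rdname synthetic_writers
#' @export
write_nuclei_images <- function(x, dir, prefix = "nuclei") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- file.path(dir, paste0(prefix, "_dapi.tiff"))
  sf <- file.path(dir, paste0(prefix, "_son.tiff"))
  sc <- function(m) m / max(max(m), 1e-9)
  EBImage::writeImage(EBImage::Image(sc(x$dapi)), df, bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(sc(x$son)), sf, bits.per.sample = 16L)
  tr <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(x$truth, tr, dataframe = "columns", na = "null",
                       auto_unbox = TRUE)
  invisible(c(df, sf, tr))
}

#' Read a binned coverage bedGraph written by [write_son_tracks()]
#'
#' @param path bedGraph file path.
#' @return data.frame with chrom, start, end, count.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          stringsAsFactors = FALSE)
  df
}

#' Read an expression TSV written by [write_expression_panel()]
#'
#' @param path TSV path (first column gene ids, remaining columns samples).
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
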