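# harmonic sums used throughout (Watterson's a_n etc.)
harmonic1 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1))
harmonic2 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1)^2)

# unfolded site frequency spectrum of a binary matrix: derived count per
# segregating column (columns with missing data dropped listwise)
unfolded_sfs <- function(bm) {
  x <- bm$x
  complete <- colSums(is.na(x)) == 0
  dc <- derived_counts(x[, complete, drop = FALSE], bm$counts)
  dc[dc > 0 & dc < bm$n]
}

#' Scaled-mutation-rate estimators for one sample
#'
#' Computes, per segment (not per bp), the standard estimators of the
#' population mutation parameter Theta: `theta_pi` (mean pairwise
#' differences), `theta_S` (Watterson, S over the harmonic number a_n),
#' `theta_H` (Fay-Wu, weighted by squared derived-allele counts),
#' `theta_L` (Zeng, linearly weighted), `theta_k` (Ewens: theta solving
#' E[K | theta, n] = k), and `theta_G` (homozygosity-based,
#' Zouros/Chakraborty: (1-F)/F with F the unbiased haplotype
#' homozygosity).  Per-bp nucleotide diversity `pi_bp` uses the segment
#' length.
#'
#' @param bm a polarized `binary_matrix` with `n >= 2`.
#' @return Object of class `theta_estimates` (also a list): the estimators
#'   plus `n`, `S`, `k`.
#' @export
theta_estimators <- function(bm) {
  n <- bm$n
  if (n < 2) stop("need at least 2 chromosomes")
  sfs <- unfolded_sfs(bm)
  S <- length(sfs)
  k <- nrow(bm$x)
  denom <- n * (n - 1)
  theta_pi <- sum(2 * sfs * (n - sfs)) / denom
  theta_S <- S / harmonic1(n)
  theta_H <- sum(2 * sfs^2) / denom
  theta_L <- sum(sfs) / (n - 1)
  G <- gene_diversity(bm$counts, n)
  Fhom <- 1 - G
  theta_G <- if (Fhom > 0) (1 - Fhom) / Fhom else Inf
  structure(list(
    theta_pi = theta_pi, theta_S = theta_S, theta_H = theta_H,
    theta_L = theta_L, theta_k = theta_k_estimate(n, k),
    theta_G = theta_G,
    pi_bp = theta_pi / bm$segment_length_bp,
    n = n, S = S, k = k
  ), class = "theta_estimates")
}

#' @export
print.theta_estimates <- function(x, ...) {
  cat(sprintf("n = %d, S = %d, k = %d\n", x$n, x$S, x$k))
  cat(sprintf("theta_pi = %.4g  theta_S = %.4g  theta_H = %.4g  theta_k = %.4g  theta_G = %.4g\n",
              x$theta_pi, x$theta_S, x$theta_H, x$theta_k, x$theta_G))
  cat(sprintf("pi per bp = %.4g\n", x$pi_bp))
  invisible(x)
}

# unbiased gene (haplotype) diversity G = n/(n-1) (1 - sum p_i^2)
gene_diversity <- function(counts, n = sum(counts)) {
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# Ewens theta_k: solves E[K | theta, n] = k
theta_k_estimate <- function(n, k) {
  if (k <= 1) return(0)
  if (k >= n) return(Inf)
  f <- function(th) sum(th / (th + 0:(n - 1))) - k
  uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
}

# expected K under the Ewens sampling formula
ewens_expected_k <- function(n, theta) {
  if (theta <= 0) return(1)
  sum(theta / (theta + 0:(n - 1)))
}

# log unsigned Stirling numbers of the first kind, row n (cached)
.stirling_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- c(-Inf, 0, rep(-Inf, n - 1))          # |s(1, k)|, k = 0..n
  for (m in seq_len(n - 1)) {
    lm <- log(m)
    shifted <- c(-Inf, row[seq_len(n)])        # |s(m, k-1)|
    row <- pmax(row + lm, shifted) +
      log1p(exp(-abs((row + lm) - shifted)))
    row[is.nan(row)] <- -Inf
  }
  .stirling_cache[[key]] <- row
  row
}

#' Distribution of the number of distinct alleles under the Ewens formula
#'
#' P(K = k | theta, n) = |s(n, k)| theta^k / theta^(n) with |s| unsigned
#' Stirling numbers of the first kind, computed in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation rate.
#' @return Numeric vector of probabilities for k = 1..n.
#' @export
ewens_k_distribution <- function(n, theta) {
  if (theta <= 0) return(c(1, rep(0, n - 1)))
  ls <- log_stirling_row(n)[-1]                # k = 1..n
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Tajima's D with p-value
#'
#' D = (theta_pi - theta_S) / sqrt(e1 S + e2 S(S-1)) with Tajima's
#' variance constants.  The p-value is the lower-tail probability
#' P(D_null <= D): `"beta-approx"` uses Tajima's bounded-beta
#' approximation; `"coalescent-null"` simulates neutral constant-size
#' genealogies conditional on the observed S.
#'
#' @param bm a `binary_matrix`.
#' @param p_method `"beta-approx"` or `"coalescent-null"`.
#' @param reps replicates for the coalescent null.
#' @return list with `D`, `p`, and the method used.
#' @export
tajima_d <- function(bm, p_method = c("beta-approx", "coalescent-null"),
                     reps = 10000) {
  p_method <- match.arg(p_method)
  th <- theta_estimators(bm)
  n <- th$n; S <- th$S
  if (S == 0) return(list(D = NA_real_, p = NA_real_, method = p_method,
                          note = "undefined: no segregating sites"))
  a1 <- harmonic1(n); a2 <- harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (th$theta_pi - th$theta_S) / sqrt(e1 * S + e2 * S * (S - 1))
  p <- if (p_method == "beta-approx") {
    Dmin <- (2 / n - 1 / a1) / sqrt(e2)
    Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
    alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
    beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
    stats::pbeta((D - Dmin) / (Dmax - Dmin), beta, alpha)
  } else {
    sim <- cpp_coal_null(n, reps, S, 0)
    Dsim <- (sim[, "pi"] - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
    mean(Dsim <= D)
  }
  list(D = D, p = p, method = p_method)
}

#' Fu's Fs with p-value
#'
#' S' = P(K >= k_obs | theta = theta_pi, n) by the exact Ewens sampling
#' formula (unsigned Stirling numbers in log space);
#' Fs = ln(S' / (1 - S')).  The p-value is P(Fs_null <= Fs) from neutral
#' constant-size coalescent simulations at theta = theta_pi, each
#' replicate's Fs computed with its own simulated theta_pi.
#'
#' @param bm a `binary_matrix`.
#' @param reps null replicates (0 skips the p-value).
#' @return list with `S_prime`, `Fs`, `p`.
#' @export
fu_fs <- function(bm, reps = 10000) {
  th <- theta_estimators(bm)
  if (th$theta_pi <= 0)
    return(list(S_prime = NA_real_, Fs = NA_real_, p = NA_real_,
                note = "undefined: theta_pi = 0"))
  n <- th$n
  fs_of <- function(k, theta) {
    if (theta <= 0) return(NA_real_)
    pk <- ewens_k_distribution(n, theta)
    Sp <- sum(pk[k:n])
    if (Sp >= 1) Inf else if (Sp <= 0) -Inf else log(Sp / (1 - Sp))
  }
  pk <- ewens_k_distribution(n, th$theta_pi)
  S_prime <- sum(pk[th$k:n])
  Fs <- if (S_prime >= 1) Inf else log(S_prime / (1 - S_prime))
  p <- NA_real_
  if (reps > 0 && is.finite(Fs)) {
    sim <- cpp_coal_null(n, reps, -1L, th$theta_pi)
    Fsim <- vapply(seq_len(reps), function(i)
      fs_of(max(1L, as.integer(sim[i, "k"])), sim[i, "pi"]), 0)
    p <- mean(Fsim[is.finite(Fsim)] <= Fs)
  }
  list(S_prime = S_prime, Fs = Fs, p = p)
}

#' Fay and Wu's H with normalization and p-value
#'
#' Raw H = theta_pi - theta_H (identically; requires polarized data).
#' The normalized statistic follows Zeng et al.:
#' (theta_pi - theta_L) / sqrt(Var), with the variance estimated from
#' theta_S and S(S-1)/(a1^2 + a2).  The p-value is the lower tail of the
#' normalized statistic under neutral constant-size coalescent
#' simulations conditional on S.
#'
#' @param bm a polarized `binary_matrix`.
#' @param reps null replicates (0 skips the p-value).
#' @return list with `H`, `H_normalized`, `p`.
#' @export
fay_wu_h <- function(bm, reps = 10000) {
  th <- theta_estimators(bm)
  n <- th$n; S <- th$S
  if (S == 0) return(list(H = NA_real_, H_normalized = NA_real_,
                          p = NA_real_, note = "undefined: S = 0"))
  a1 <- harmonic1(n); a2 <- harmonic2(n)
  H <- th$theta_pi - th$theta_H
  tw <- th$theta_S
  th2 <- S * (S - 1) / (a1^2 + a2)
  bn1 <- a2 + 1 / n^2
  v <- (n - 2) / (6 * (n - 1)) * tw +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * th2
  Hn <- (th$theta_pi - th$theta_L) / sqrt(v)
  p <- NA_real_
  if (reps > 0) {
    sim <- cpp_coal_null(n, reps, S, 0)
    Hn_sim <- (sim[, "pi"] - sim[, "thetaL"]) / sqrt(v)
    p <- mean(Hn_sim <= Hn)
  }
  list(H = H, H_normalized = Hn, p = p)
}

#' Ewens-Watterson, Slatkin and Chakraborty haplotype tests
#'
#' Haplotype-configuration tests based on the Ewens sampling formula:
#' \describe{
#' \item{Ewens-Watterson}{expected homozygosity and
#'   p = P(F_null <= F_obs) with F the (unbiased) haplotype homozygosity,
#'   sampling configurations from the Ewens formula conditional on (n, k).}
#' \item{Slatkin}{exact test ordering configurations by their conditional
#'   Ewens probability: p = P(Pr(config_null) <= Pr(config_obs)).}
#' \item{Chakraborty}{population-amalgamation test: expected number of
#'   haplotypes E[K] = sum theta/(theta+i) at theta = theta_pi, and
#'   P(K >= k_obs) from the exact Ewens distribution.}
#' }
#' Conditional sampling uses the Chinese-restaurant construction at the
#' theta solving E[K] = k, with rejection on K = k.
#'
#' @param bm a `binary_matrix`.
#' @param reps Monte-Carlo replicates for the conditional tests.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return list with elements `observed_homozygosity`,
#'   `expected_homozygosity`, `watterson_p`, `slatkin_p`, `chakraborty`
#'   (list `k_exp`, `p_k_or_more`), `k`, `n`.
#' @export
ewens_based_tests <- function(bm, reps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 1000) warning("reps < 1000: Monte-Carlo p-values will be crude")
  n <- bm$n
  k <- nrow(bm$x)
  if (k > n) stop("more haplotypes than chromosomes")
  th <- theta_estimators(bm)
  F_obs <- 1 - gene_diversity(bm$counts, n)
  # observed conditional config probability (Slatkin criterion),
  # theta-free part given K
  log_config <- function(counts) {
    tab <- table(counts[counts > 0])
    lgamma(n + 1) - sum(tab * log(as.integer(names(tab)))) -
      sum(lgamma(tab + 1))
  }
  lc_obs <- log_config(bm$counts)
  # sample ESF configurations conditional on K = k by rejection
  thk <- theta_k_estimate(n, k)
  acc_F <- numeric(0); acc_lc <- numeric(0)
  tries <- 0
  while (length(acc_F) < reps && tries < 60) {
    m <- cpp_crp(n, thk, reps * 2L)
    keep <- m[, "K"] == k
    ss <- m[keep, "sum_sq"]
    Fu <- 1 - n / (n - 1) * (1 - ss / n^2)   # unbiased homozygosity
    acc_F <- c(acc_F, Fu)
    acc_lc <- c(acc_lc, m[keep, "log_config"])
    tries <- tries + 1
  }
  if (length(acc_F) < reps)
    warning("conditional rejection sampling accepted only ",
            length(acc_F), " configurations")
  acc_F <- head(acc_F, reps); acc_lc <- head(acc_lc, reps)
  pk <- ewens_k_distribution(n, th$theta_pi)
  list(
    observed_homozygosity = F_obs,
    expected_homozygosity = mean(acc_F),
    watterson_p = mean(acc_F <= F_obs),
    slatkin_p = mean(acc_lc <= lc_obs + 1e-12),
    chakraborty = list(k_exp = ewens_expected_k(n, th$theta_pi),
                       p_k_or_more = sum(pk[k:n])),
    theta_k = thk, k = k, n = n
  )
}

#' Pairwise and global Phi-ST from haplotype data
#'
#' AMOVA-style fixation indices computed from the matrix of pairwise
#' mutation differences between haplotypes: the among-population variance
#' component over the total.  Populations with fewer than 2 chromosomes
#' are excluded with a warning.
#'
#' @param ds a polarized [haplotype_dataset()].
#' @param populations populations to include (default: all).
#' @return list with `global` and `pairwise` (symmetric matrix).
#' @export
pairwise_fst <- function(ds, populations = NULL) {
  pn <- ds$populations$name
  if (is.null(populations)) populations <- pn
  sizes <- colSums(ds$counts[, match(populations, pn), drop = FALSE])
  small <- populations[sizes < 2]
  if (length(small)) {
    warning("excluding populations with n < 2: ",
            paste(small, collapse = ", "))
    populations <- setdiff(populations, small)
  }
  if (length(populations) < 2) stop("need at least two populations with n >= 2")
  bm <- as_binary_matrix(ds)
  x <- replace(bm$x, is.na(bm$x), 0L)
  dm <- as.matrix(stats::dist(x, method = "manhattan"))
  cnt <- ds$counts[match(bm$haplotype_id, rownames(ds$alleles)),
                   match(populations, pn), drop = FALSE]
  phi <- function(pops) {
    cc <- cnt[, pops, drop = FALSE]
    np <- colSums(cc); n <- sum(np); P <- length(pops)
    # weighted SSD from haplotype-level distances
    ssd_wp <- 0
    for (p in seq_len(P)) {
      w <- cc[, p]
      ssd_wp <- ssd_wp + sum((w %o% w) * dm) / (2 * np[p])
    }
    wtot <- rowSums(cc)
    ssd_tot <- sum((wtot %o% wtot) * dm) / (2 * n)
    ssd_ap <- ssd_tot - ssd_wp
    sigma_w <- ssd_wp / (n - P)
    ncoef <- (n - sum(np^2) / n) / (P - 1)
    sigma_a <- (ssd_ap / (P - 1) - sigma_w) / ncoef
    # negative among-population components (sampling noise around zero
    # differentiation) are truncated at zero, as is conventional
    if (sigma_a <= 0 || sigma_a + sigma_w <= 0) 0
    else sigma_a / (sigma_a + sigma_w)
  }
  P <- length(populations)
  pw <- matrix(NA_real_, P, P, dimnames = list(populations, populations))
  for (a in seq_len(P)) for (b in seq_len(a - 1)) {
    pw[a, b] <- pw[b, a] <- phi(c(a, b))
  }
  diag(pw) <- 0
  list(global = phi(seq_len(P)), pairwise = pw)
}

#' Full diversity and neutrality report for one sample
#'
#' Bundles the estimators and all implemented neutrality tests into one
#' object (one column of a diversity/neutrality table).
#'
#' @param bm a polarized `binary_matrix`.
#' @param reps Monte-Carlo replicates for simulation-based p-values.
#' @param seed integer seed for the stochastic tests.
#' @return Object of class `neutrality_report`.
#' @export
neutrality_report <- function(bm, reps = 10000, seed = 1) {
  set.seed(seed)
  th <- theta_estimators(bm)
  G <- gene_diversity(bm$counts, bm$n)
  td <- tajima_d(bm, "coalescent-null", reps = reps)
  td_beta <- tajima_d(bm, "beta-approx")
  fs <- fu_fs(bm, reps = reps)
  fw <- if (th$S > 0) fay_wu_h(bm, reps = reps) else
    list(H = NA, H_normalized = NA, p = NA)
  ew <- ewens_based_tests(bm, reps = reps)
  structure(list(
    n = bm$n, S = th$S, k = th$k,
    theta = th, gene_diversity = G, homozygosity = 1 - G,
    tajima = td, tajima_beta = td_beta, fu = fs, fay_wu = fw, ewens = ew
  ), class = "neutrality_report")
}

#' @export
print.neutrality_report <- function(x, ...) {
  cat(sprintf("n = %d  k = %d  S = %d\n", x$n, x$k, x$S))
  cat(sprintf("theta_pi = %.3f  theta_S = %.3f  theta_H = %.3f  (pi/bp = %.3g)\n",
              x$theta$theta_pi, x$theta$theta_S, x$theta$theta_H,
              x$theta$pi_bp))
  cat(sprintf("homozygosity (1-G) = %.3f (Ewens-Watterson expected %.3f, Watterson p = %.3f, Slatkin p = %.3f)\n",
              x$homozygosity, x$ewens$expected_homozygosity,
              x$ewens$watterson_p, x$ewens$slatkin_p))
  cat(sprintf("Chakraborty: k_exp = %.2f, P(k or more) = %.3f\n",
              x$ewens$chakraborty$k_exp, x$ewens$chakraborty$p_k_or_more))
  cat(sprintf("Tajima D = %.3f (p = %.3f)\n", x$tajima$D, x$tajima$p))
  cat(sprintf("Fu Fs = %.3f (p = %.3f)\n", x$fu$Fs, x$fu$p))
  cat(sprintf("Fay-Wu H = %.3f, normalized = %.3f (p = %.3f)\n",
              x$fay_wu$H, x$fay_wu$H_normalized, x$fay_wu$p))
  invisible(x)
}
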