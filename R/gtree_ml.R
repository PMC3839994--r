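# convert a gene_tree to the 0-based parent / tip-multiplicity arrays used
# by the compiled importance-sampling engine
gt_arrays <- function(gt) {
  list(parent = gt$parent - 1L, tipmult = gt$tip_mult)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Griffiths-Tavare importance-sampling log-likelihood of a gene tree
#'
#' Estimates the probability of the observed sample configuration under
#' the infinite-sites coalescent, conditional on the rooted gene tree, by
#' importance sampling over mutation/coalescence histories: event times
#' are proposed from the total event intensity and events chosen among
#' the feasible transitions in proportion to their rates (the classical
#' Griffiths-Tavare backward-urn scheme).  Constant population size
#' (`beta = 0`) or exponential growth `N(t) = N0 exp(-beta t)` backward
#' in time, with t in coalescent units (1.5 N0 generations for X-linked
#' data) and mutation rate `theta/2` per lineage.
#'
#' The estimate is unbiased up to a combinatorial constant that does not
#' depend on `theta` or `beta`, so likelihood ratios and maxima are exact
#' in expectation.
#'
#' @param gt a `gene_tree` (see [build_gene_tree()]).
#' @param theta scaled mutation rate (per segment).
#' @param beta exponential growth rate (0 = constant size).
#' @param budget number of sampled histories.
#' @param seed optional integer seed.
#' @param proposal `"gt"` (Griffiths-Tavare backward urn) or `"sd"`
#'   (Stephens-Donnelly refinement; much lower weight variance on large
#'   samples).
#' @return list with `logL`, `se_logL` (delta-method Monte-Carlo SE on the
#'   log scale), `ess` (effective sample size), `budget`.
#' @export
gt_loglik <- function(gt, theta, beta = 0, budget = 1e5, seed = NULL,
                      proposal = c("sd", "gt")) {
  proposal <- match.arg(proposal)
  stopifnot(theta > 0 || length(gt$parent) == 1)
  if (!is.null(seed)) set.seed(seed)
  a <- gt_arrays(gt)
  run <- cpp_gt_run(a$parent, a$tipmult, theta, beta, as.integer(budget),
                    FALSE, numeric(), match(proposal, c("gt", "sd")) - 1L)
  lw <- run$logw
  logL <- logsumexp(lw) - log(length(lw))
  wrel <- exp(lw - max(lw))
  se <- sd(wrel) / (mean(wrel) * sqrt(length(lw)))
  list(logL = logL, se_logL = se,
       ess = sum(wrel)^2 / sum(wrel^2), budget = length(lw))
}

# one driving run whose histories can be re-weighted to any (theta, beta):
# log w(theta, beta) = logw0 + (beta - beta0) Tc + M log(theta/theta0)
#                      - (theta - theta0) A / 2 - (C(beta) - C(beta0))
gt_driving_run <- function(gt, theta0, beta0, budget, beta_grid, seed = NULL,
                           collect_ages = FALSE, proposal = "sd") {
  if (!is.null(seed)) set.seed(seed)
  a <- gt_arrays(gt)
  bg <- unique(c(beta0, beta_grid))
  run <- cpp_gt_run(a$parent, a$tipmult, theta0, beta0, as.integer(budget),
                    collect_ages, bg, match(proposal, c("gt", "sd")) - 1L)
  run$beta_grid <- bg
  run$theta0 <- theta0
  run$beta0 <- beta0
  run$M <- length(gt$parent) - 1L
  run
}

reweight_logw <- function(run, theta, beta) {
  g <- match(beta, run$beta_grid)
  if (is.na(g)) stop("beta not in the driving run's beta grid")
  g0 <- match(run$beta0, run$beta_grid)
  run$logw + (beta - run$beta0) * run$Tc +
    run$M * (log(theta) - log(run$theta0)) -
    (theta - run$theta0) * run$A / 2 -
    (run$Cb[, g] - run$Cb[, g0])
}

reweight_logL <- function(run, theta, beta) {
  lw <- reweight_logw(run, theta, beta)
  B <- length(lw)
  wrel <- exp(lw - max(lw))
  c(logL = logsumexp(lw) - log(B),
    se = sd(wrel) / (mean(wrel) * sqrt(B)),
    ess = sum(wrel)^2 / sum(wrel^2))
}

#' Importance-sampling likelihood surface over a parameter grid
#'
#' Evaluates the log-likelihood on a (theta, beta) grid from a single
#' driving run: every grid point re-weights the same sampled histories
#' (the sufficient statistics of each history under any (theta, beta) are
#' closed-form), which makes the surface smooth in the parameters and the
#' argmax far more stable at a given budget than independent runs.  The
#' driving point defaults to the grid centre.  A warning is issued when
#' the Monte-Carlo SEs of the top two points overlap, i.e. the budget is
#' too small for a stable argmax.
#'
#' @param gt a `gene_tree`.
#' @param model `"constant"` (beta fixed at 0) or `"growth"`.
#' @param theta_grid,beta_grid numeric grids (`beta_grid` ignored for the
#'   constant model).
#' @param budget histories in the driving run.
#' @param seed integer seed.
#' @param driving optional `c(theta, beta)` driving point.
#' @return Object of class `likelihood_surface`: data.frame `grid`
#'   (theta, beta, logL, se, ess), `theta_ml`, `beta_ml` (quadratically
#'   interpolated in log-theta), `logL_ml`.
#' @export
likelihood_surface <- function(gt, model = c("constant", "growth"),
                               theta_grid, beta_grid = 0,
                               budget = 1e5, seed = 1, driving = NULL) {
  model <- match.arg(model)
  if (model == "constant") beta_grid <- 0
  if (!length(theta_grid)) stop("empty theta grid")
  theta_grid <- sort(theta_grid)
  if (is.null(driving))
    driving <- c(exp(mean(log(range(theta_grid)))), stats::median(beta_grid))
  run <- gt_driving_run(gt, driving[1], driving[2], budget, beta_grid,
                        seed = seed)
  pts <- expand.grid(theta = theta_grid, beta = beta_grid)
  res <- vapply(seq_len(nrow(pts)),
                function(i) reweight_logL(run, pts$theta[i], pts$beta[i]),
                numeric(3))
  grid <- cbind(pts, logL = res[1, ], se = res[2, ], ess = res[3, ])
  best <- which.max(grid$logL)
  o <- order(grid$logL, decreasing = TRUE)
  if (nrow(grid) > 1 &&
      grid$logL[o[1]] - grid$logL[o[2]] < grid$se[o[1]] + grid$se[o[2]] &&
      abs(grid$theta[o[1]] - grid$theta[o[2]]) >
        0.25 * abs(diff(range(theta_grid))))
    warning("IS budget too small for a stable argmax: ",
            "SEs of well-separated top grid points overlap; consider budget >= ",
            format(budget * 10, scientific = TRUE))
  # refine theta by quadratic interpolation at the best beta
  bb <- grid$beta[best]
  sub <- grid[grid$beta == bb, ]
  theta_ml <- quad_argmax(log(sub$theta), sub$logL, exp = TRUE)
  structure(list(grid = grid,
                 theta_ml = theta_ml, beta_ml = bb,
                 logL_ml = grid$logL[best],
                 boundary = grid$theta[best] %in% range(theta_grid),
                 driving = driving, budget = budget, seed = seed,
                 run = run),
            class = "likelihood_surface")
}

#' @export
print.likelihood_surface <- function(x, ...) {
  cat(sprintf("likelihood surface (%d points, driving budget %g)\n",
              nrow(x$grid), x$budget))
  cat(sprintf("ML: theta = %.4g, beta = %.4g (logL = %.3f)\n",
              x$theta_ml, x$beta_ml, x$logL_ml))
  invisible(x)
}

#' Two-stage profile search for (theta, beta) under exponential growth
#'
#' Reproduces the staged grid procedure: first explore the growth rate
#' beta at theta fixed to its constant-size ML value, then explore theta
#' at the selected beta, re-driving the importance sampler at the current
#' optimum each round.
#'
#' @param gt a `gene_tree`.
#' @param theta_start starting theta (e.g. the constant-size MLE).
#' @param beta_grid grid of growth rates for the first stage.
#' @param theta_factors multiplicative grid around the current theta for
#'   the second stage.
#' @param rounds alternation rounds.
#' @param budget histories per driving run.
#' @param seed base seed.
#' @return list with `theta_ml`, `beta_ml`, and the stage surfaces.
#' @export
profile_growth_search <- function(gt, theta_start,
                                  beta_grid = seq(0, 2, by = 0.2),
                                  theta_factors = seq(0.7, 1.6, by = 0.1),
                                  rounds = 4, budget = 1e5, seed = 1) {
  theta <- theta_start
  beta <- 0
  stages <- list()
  best_logL <- -Inf
  for (r in seq_len(rounds)) {
    s1 <- likelihood_surface(gt, "growth", theta_grid = theta,
                             beta_grid = beta_grid, budget = budget,
                             seed = seed + 1000 * r,
                             driving = c(theta, if (r == 1)
                               stats::median(beta_grid) else beta))
    beta_new <- s1$grid$beta[which.max(s1$grid$logL)]
    s2 <- likelihood_surface(gt, "growth",
                             theta_grid = theta * theta_factors,
                             beta_grid = beta_new, budget = budget,
                             seed = seed + 1000 * r + 500,
                             driving = c(theta, beta_new))
    stages[[r]] <- list(beta_stage = s1, theta_stage = s2)
    # stop when the round no longer improves the likelihood beyond the
    # Monte-Carlo noise of the surface (the printed-procedure criterion:
    # results constant over repeated runs)
    tol <- 2 * stats::median(s2$grid$se)
    if (s2$logL_ml < best_logL + tol && r > 1) break
    best_logL <- s2$logL_ml
    beta <- beta_new
    theta <- s2$theta_ml
  }
  list(theta_ml = theta, beta_ml = beta, stages = stages)
}

#' Posterior mean ages of mutations and the TMRCA by importance sampling
#'
#' At fixed (theta, beta) — typically the maximum-likelihood values — the
#' importance-sampling weights give the posterior mean and SD of every
#' mutation's age and of the TMRCA, in coalescent units, generations and
#' years.  Conversion uses `N0 = theta / (3 mu)`: one coalescent unit is
#' `1.5 N0 = theta / (2 mu)` generations.
#'
#' @param gt a `gene_tree`.
#' @param theta,beta model parameters.
#' @param budget number of histories.
#' @param seed integer seed.
#' @param cal a [calibrate_rate()] object (NULL: report coalescent units
#'   only).
#' @return Object of class `age_posterior`: data.frame `ages` (TMRCA row
#'   first; columns mean/sd in units, generations, years), `ess`, `N0`.
#' @export
estimate_ages <- function(gt, theta, beta = 0, budget = 1e5, seed = 1,
                          cal = calibrate_rate()) {
  run <- gt_driving_run(gt, theta, beta, budget, beta, seed = seed,
                        collect_ages = TRUE)
  lw <- run$logw
  keep <- is.finite(lw)
  w <- exp(lw[keep] - max(lw[keep]))
  w <- w / sum(w)
  wmean <- function(x) sum(w * x)
  wsd <- function(x) sqrt(max(0, sum(w * x^2) - sum(w * x)^2))
  mat <- cbind(run$tmrca[keep], run$ages[keep, -1, drop = FALSE])
  labels <- c("TMRCA", gt$mutation[-1])
  mu <- if (is.null(cal)) NA_real_ else cal$mu_segment
  units_to_gens <- if (is.na(mu) || mu <= 0) NA_real_ else theta / (2 * mu)
  gy <- if (is.null(cal)) NA_real_ else cal$generation_years
  ages <- data.frame(
    focal = labels,
    mean_units = apply(mat, 2, wmean),
    sd_units = apply(mat, 2, wsd),
    order_arbitrary = c(FALSE, gt$order_arbitrary[-1])
  )
  ages$generations <- ages$mean_units * units_to_gens
  ages$sd_generations <- ages$sd_units * units_to_gens
  ages$years <- ages$generations * gy
  ages$sd_years <- ages$sd_generations * gy
  structure(list(ages = ages, theta = theta, beta = beta,
                 ess = 1 / sum(w^2),
                 N0 = if (is.na(mu) || mu <= 0) NA_real_ else
                   n0_from_theta(theta, cal),
                 budget = budget),
            class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat(sprintf("coalescent age estimates at theta = %.4g, beta = %.4g",
              x$theta, x$beta))
  if (!is.na(x$N0)) cat(sprintf(" (N0 = %.0f)", x$N0))
  cat(sprintf(", ESS = %.0f\n", x$ess))
  df <- x$ages
  df$years_ky <- df$years / 1000
  df$sd_ky <- df$sd_years / 1000
  print(df[, c("focal", "mean_units", "sd_units", "generations",
               "years_ky", "sd_ky", "order_arbitrary")], digits = 3)
  invisible(x)
}

#' Effective population size from theta
#'
#' For an X-linked locus theta = 3 N0 mu, so N0 = theta / (3 mu) with mu
#' the per-segment per-generation mutation rate.
#'
#' @param theta scaled mutation rate.
#' @param cal a [calibrate_rate()] object.
#' @return N0 (diploid effective size).
#' @export
n0_from_theta <- function(theta, cal = calibrate_rate()) {
  if (theta <= 0) stop("theta must be positive")
  if (cal$mu_segment <= 0) stop("mutation rate is zero")
  theta / (3 * cal$mu_segment)
}

# exhaustive Ethier-Griffiths-Tavare recursion for tiny gene trees,
# constant size: exact configuration probability (same normalization as
# the IS engine).  Used as an independent oracle in the tests.
gt_exact_prob <- function(gt, theta) {
  parent <- gt$parent
  V <- length(parent)
  memo <- new.env(parent = emptyenv())
  rec <- function(cnt) {
    n <- sum(cnt)
    if (n == 1 && cnt[1] == 1) return(1)
    key <- paste(cnt, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    act_below <- cnt
    for (v in rev(seq_len(V)[-1]))
      act_below[parent[v]] <- act_below[parent[v]] + act_below[v]
    p <- 0
    denom <- n * (n - 1 + theta)
    for (v in seq_len(V)) {
      if (cnt[v] >= 2) {
        c2 <- cnt; c2[v] <- c2[v] - 1L
        p <- p + cnt[v] * (cnt[v] - 1) / denom * rec(c2)
      }
      if (v > 1 && cnt[v] == 1 && act_below[v] == 1) {
        c2 <- cnt; c2[v] <- 0L; c2[parent[v]] <- c2[parent[v]] + 1L
        p <- p + theta / denom * rec(c2)
      }
    }
    memo[[key]] <- p
    p
  }
  rec(gt$tip_mult)
}
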