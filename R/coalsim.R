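#' Describe a demographic model for the infinite-sites coalescent simulator
#'
#' Time runs backward in coalescent units of `1.5 N0` generations
#' (X-linked scaling), where `N0` is the present total (metapopulation)
#' effective size; `theta = 3 N0 mu` per segment.  The relative total size
#' at time t is piecewise `size * exp(-beta (t - t_start))` per epoch.
#' With `n_demes > 1` the total is split into equal demes joined by
#' symmetric conservative migration; `migration_4Nm` is `4 N m` with `N`
#' the present deme size.  `merge_time` (coalescent units) moves all
#' lineages into a single deme at that time backward (forward: the
#' population split into demes at that moment).
#'
#' @param theta scaled mutation rate per segment.
#' @param n_samples chromosomes sampled per deme (recycled to `n_demes`).
#' @param n_demes number of demes.
#' @param migration_4Nm scaled migration rate (required positive when
#'   `n_demes > 1` unless `merge_time` is finite).
#' @param epochs data.frame with columns `t_start`, `size`, `beta`
#'   describing the relative total size backward in time; default constant
#'   size 1.
#' @param merge_time time at which demes merge backward (Inf = never):
#'   forward in time, a panmictic population that split into demes then.
#' @param scatter_time time at which the sample's single panmictic
#'   population scatters into the demes backward (Inf = never): forward in
#'   time, subdivided demes that fused into one population then.
#' @param segment_length_bp nominal segment length used when emitting
#'   haplotype tables.
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(theta, n_samples, n_demes = 1,
                              migration_4Nm = 0,
                              epochs = data.frame(t_start = 0, size = 1,
                                                  beta = 0),
                              merge_time = Inf, scatter_time = Inf,
                              segment_length_bp = 11024) {
  n_samples <- rep_len(n_samples, n_demes)
  stopifnot(theta >= 0, all(n_samples >= 0), sum(n_samples) >= 2,
            migration_4Nm >= 0, nrow(epochs) >= 1,
            !is.unsorted(epochs$t_start), epochs$t_start[1] == 0)
  if (is.finite(merge_time) && is.finite(scatter_time))
    stop("merge_time and scatter_time cannot both be finite")
  if (n_demes > 1 && migration_4Nm == 0 && !is.finite(merge_time))
    stop("non-coalescing demes: n_demes > 1 needs migration_4Nm > 0 or a finite merge_time")
  structure(list(theta = theta, n_samples = n_samples, n_demes = n_demes,
                 migration_4Nm = migration_4Nm, epochs = epochs,
                 merge_time = merge_time, scatter_time = scatter_time,
                 segment_length_bp = segment_length_bp),
            class = "demographic_model")
}

# relative total size at time t
model_nu <- function(model, t) {
  e <- model$epochs
  i <- findInterval(t, e$t_start)
  e$size[i] * exp(-e$beta[i] * (t - e$t_start[i]))
}

# next-event time for an inhomogeneous rate P / nu(t) starting at t0,
# honouring epoch boundaries: returns min(candidate, boundary)
next_coal_time <- function(model, P, t0) {
  if (P <= 0) return(Inf)
  e <- model$epochs
  repeat {
    i <- findInterval(t0, e$t_start)
    t_end <- if (i < nrow(e)) e$t_start[i + 1] else Inf
    s0 <- e$size[i] * exp(-e$beta[i] * (t0 - e$t_start[i]))
    E <- rexp(1)
    if (e$beta[i] == 0) {
      cand <- t0 + E * s0 / P
    } else {
      # rate P/nu = (P/s0) exp(beta (t - t0)); closed-form inverse
      b <- e$beta[i]
      arg <- 1 + b * E * s0 / P
      cand <- if (arg <= 0) Inf else t0 + log(arg) / b
    }
    if (cand <= t_end) return(cand)
    t0 <- t_end
    if (!is.finite(t0)) return(Inf)
  }
}

#' Simulate samples under the structured infinite-sites coalescent
#'
#' Exact backward simulation of the (structured) coalescent under the
#' model, with Poisson mutations at rate `theta/2` per lineage per unit
#' time (infinite sites: every mutation is a new column).  Each replicate
#' returns the haplotype matrix, the genealogy and its TMRCA.
#'
#' @param model a [demographic_model()].
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return list of `reps` samples; each is a list with `matrix`
#'   (chromosomes x mutations, 0/1), `deme` (per chromosome), `tmrca`,
#'   `total_length`, `S`, and `genealogy` (`parent`, `time`).
#' @export
simulate_coalescent <- function(model, reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(i) sim_one(model))
}

sim_one <- function(model) {
  n <- sum(model$n_samples)
  d <- model$n_demes
  mig_rate <- 0.375 * model$migration_4Nm * d   # per lineage per unit time
  NN <- 2L * n - 1L
  parent <- rep(NA_integer_, NN)
  ntime <- numeric(NN)
  lin <- seq_len(n)                       # active lineage node ids
  deme <- rep(seq_len(d), model$n_samples)
  scattered <- !is.finite(model$scatter_time)
  ldeme <- if (scattered) deme else rep(1L, n)
  d_eff <- if (scattered) d else 1L
  merged <- !is.finite(model$merge_time) && d == 1
  t <- 0
  nxt <- n + 1L
  while (length(lin) > 1) {
    d <- d_eff
    k_d <- tabulate(ldeme, d)
    pairs2 <- sum(k_d * (k_d - 1))        # 2 * number of within-deme pairs
    # within-deme pair coalescence rate: d / nu(t) per pair
    tc <- next_coal_time(model, pairs2 / 2 * d, t)
    tm <- if (mig_rate > 0 && d > 1 && !merged)
      t + rexp(1) / (mig_rate * length(lin)) else Inf
    tnext <- min(tc, tm)
    if (!scattered && tnext > model$scatter_time) {
      t <- model$scatter_time
      ldeme <- sample.int(model$n_demes, length(lin), replace = TRUE)
      d_eff <- model$n_demes
      scattered <- TRUE
      next
    }
    if (!merged && tnext > model$merge_time) {
      t <- model$merge_time
      ldeme[] <- 1L
      d_eff <- 1L
      merged <- TRUE
      next
    }
    if (!is.finite(tnext)) stop("internal error: no feasible event")
    t <- tnext
    if (tc <= tm) {
      w <- k_d * (k_d - 1)
      dd <- sample.int(length(w), 1, prob = w)
      idx <- which(ldeme == dd)
      pair <- idx[sample.int(length(idx), 2)]
      parent[lin[pair]] <- nxt
      ntime[nxt] <- t
      lin[pair[1]] <- nxt
      ldeme[pair[1]] <- dd
      lin <- lin[-pair[2]]
      ldeme <- ldeme[-pair[2]]
      nxt <- nxt + 1L
    } else {
      i <- sample.int(length(lin), 1)
      others <- setdiff(seq_len(d), ldeme[i])
      ldeme[i] <- others[sample.int(length(others), 1)]
    }
  }
  root <- nxt - 1L
  blen <- ntime[parent] - ntime[seq_len(NN)]
  blen[root] <- 0
  tmrca <- ntime[root]
  # tips below each node
  below <- vector("list", NN)
  for (v in seq_len(n)) below[[v]] <- v
  for (v in seq_len(NN - 1L)) {
    p <- parent[v]
    below[[p]] <- c(below[[p]], if (v <= n) v else below[[v]])
  }
  for (v in seq_len(n)) below[[v]] <- v
  nmut <- rpois(NN, model$theta / 2 * pmax(blen, 0))
  nmut[root] <- 0L
  S <- sum(nmut)
  mat <- matrix(0L, n, S)
  s <- 0L
  for (v in which(nmut > 0)) {
    tips <- if (v <= n) v else setdiff(below[[v]], 0L)
    for (m in seq_len(nmut[v])) {
      s <- s + 1L
      mat[tips, s] <- 1L
    }
  }
  list(matrix = mat, deme = deme, tmrca = tmrca,
       total_length = sum(blen), S = S,
       genealogy = list(parent = parent, time = ntime))
}

#' Convert a simulated sample to a binary_matrix
#'
#' Collapses identical chromosomes into haplotypes with counts and labels
#' mutations `m1..mS` at distinct pseudo-positions, so that the full
#' analysis pipeline (four-gamete check, gene tree, statistics) can run on
#' simulator output.
#'
#' @param sim one element of [simulate_coalescent()] output.
#' @param segment_length_bp segment length recorded on the result.
#' @return A `binary_matrix`.
#' @export
sim_binary_matrix <- function(sim, segment_length_bp = 11024) {
  mat <- sim$matrix
  n <- nrow(mat)
  key <- apply(mat, 1, paste, collapse = "")
  first <- !duplicated(key)
  x <- mat[first, , drop = FALSE]
  counts <- as.integer(table(key)[key[first]])
  S <- ncol(mat)
  labels <- if (S > 0) paste0("m", seq_len(S)) else character(0)
  colnames(x) <- labels
  dc <- derived_counts(x, counts)
  structure(list(
    x = x, counts = counts,
    haplotype_id = paste0("S", seq_len(nrow(x))),
    labels = labels,
    positions = if (S > 0) sort(sample.int(segment_length_bp, S)) else
      integer(0),
    cpg = rep(FALSE, S),
    segregating = dc > 0 & dc < n, n = n,
    segment_length_bp = segment_length_bp,
    populations = paste0("deme", seq_len(max(sim$deme)))
  ), class = "binary_matrix")
}

#' Write simulated samples in ms-compatible text format
#'
#' Emits the familiar `//` / `segsites:` / `positions:` blocks of
#' Hudson-style simulators.
#'
#' @param sims output of [simulate_coalescent()].
#' @param path output file path.
#' @param header command-line-like header string for the first line.
#' @export
write_ms <- function(sims, path, header = "xhaplo simulate") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, ""), con)
  for (sim in sims) {
    writeLines("//", con)
    S <- ncol(sim$matrix)
    writeLines(paste("segsites:", S), con)
    if (S > 0) {
      pos <- sort(runif(S))
      writeLines(paste("positions:", paste(sprintf("%.5f", pos),
                                           collapse = " ")), con)
      writeLines(apply(sim$matrix, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Demographic presets for the estimator-behaviour experiments
#'
#' Named scenarios used to study how demography moves the theta
#' estimators (see the methods vignette for the exact realizations):
#' \describe{
#' \item{constant}{panmictic constant size.}
#' \item{bottleneck}{size drops to 10 percent between 0.05 and 0.15
#'   coalescent units backward.}
#' \item{strong_subdivision}{4 demes, 4Nm = 0.04, constant total size.}
#' \item{subdivision_then_panmixia}{4 demes, 4Nm = 0.04 in the recent
#'   past only: the demes merge 500 generations back (N0 = 20,000, so
#'   0.0167 units); forward in time a panmictic population split into
#'   demes 500 generations ago.}
#' \item{five_fold_growth}{five-fold size increase 1500 generations ago
#'   (ancestral N = 4000 reference, so the jump is at 0.25 units); theta
#'   refers to the ancestral size.}
#' \item{combined_subdivision_growth}{ancient subdivision with moderate
#'   gene flow followed by growth: 4 demes with 4Nm = 2 until the demes
#'   fuse 15,000 generations ago (0.5 units at N0 = 20,000), after which
#'   the merged population grows exponentially from 7,000 to 20,000 to
#'   the present; input theta 7.5 at the present size.}
#' }
#'
#' @param name preset name.
#' @param theta input scaled mutation rate (defaults per preset).
#' @param n total sample size (split equally across demes).
#' @return A [demographic_model()].
#' @export
coalsim_preset <- function(name = c("constant", "bottleneck",
                                    "strong_subdivision",
                                    "subdivision_then_panmixia",
                                    "five_fold_growth",
                                    "combined_subdivision_growth"),
                           theta = NULL, n = 100) {
  name <- match.arg(name)
  switch(name,
    constant = demographic_model(theta %||% 5, n),
    bottleneck = demographic_model(
      theta %||% 5, n,
      epochs = data.frame(t_start = c(0, 0.05, 0.15),
                          size = c(1, 0.1, 1), beta = 0)),
    strong_subdivision = demographic_model(
      theta %||% 5, rep(ceiling(n / 4), 4), n_demes = 4,
      migration_4Nm = 0.04),
    subdivision_then_panmixia = demographic_model(
      theta %||% 5, rep(ceiling(n / 4), 4), n_demes = 4,
      migration_4Nm = 0.04, merge_time = 500 / (1.5 * 20000)),
    five_fold_growth = demographic_model(
      theta %||% 5, n,
      epochs = data.frame(t_start = c(0, 1500 / (1.5 * 4000)),
                          size = c(5, 1), beta = 0)),
    combined_subdivision_growth = demographic_model(
      theta %||% 7.5, rep(ceiling(n / 4), 4), n_demes = 4,
      migration_4Nm = 2,
      epochs = data.frame(t_start = c(0, 15000 / (1.5 * 20000)),
                          size = c(1, 7 / 20),
                          beta = c(2 * log(20 / 7), 0)),
      scatter_time = 15000 / (1.5 * 20000))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean theta estimators (pi, S, ML) under a demographic scenario
#'
#' For each simulated replicate computes theta_pi, Watterson's theta_S,
#' and the constant-size maximum-likelihood theta from the
#' Griffiths-Tavare engine on the replicate's perfect phylogeny (the
#' "analyst's view": the ML model assumes panmixia and constant size even
#' when the generating scenario does not).
#'
#' @param scenario preset name (see [coalsim_preset()]) or a
#'   [demographic_model()].
#' @param reps replicates.
#' @param seed integer seed.
#' @param ml_budget IS histories per grid point and replicate.
#' @param ml_grid_len grid points for the ML scan (multiplicative grid
#'   centred on each replicate's Watterson estimate).
#' @param theta,n forwarded to [coalsim_preset()].
#' @return list with `summary` (means and SDs of the three estimators)
#'   and `per_rep` (data.frame).
#' @export
theta_response_experiment <- function(scenario, reps = 500, seed = 1,
                                      ml_budget = 200, ml_grid_len = 11,
                                      theta = NULL, n = 100) {
  model <- if (inherits(scenario, "demographic_model")) scenario
           else coalsim_preset(scenario, theta = theta, n = n)
  set.seed(seed)
  out <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("theta_pi", "theta_S", "theta_ML")))
  for (r in seq_len(reps)) {
    sim <- sim_one(model)
    bm <- sim_binary_matrix(sim, model$segment_length_bp)
    nn <- bm$n
    sfs <- unfolded_sfs(bm)
    S <- length(sfs)
    tpi <- sum(2 * sfs * (nn - sfs)) / (nn * (nn - 1))
    tS <- S / harmonic1(nn)
    out[r, 1] <- tpi
    out[r, 2] <- tS
    if (S == 0) { out[r, 3] <- 0; next }
    gt <- build_gene_tree(bm)
    centre <- max(tS, 0.5)
    run <- gt_driving_run(gt, centre, 0, ml_budget, 0)
    grid <- centre * 2^seq(-1.6, 1.6, length.out = ml_grid_len)
    ll <- vapply(grid, function(th) reweight_logL(run, th, 0)[["logL"]], 0)
    out[r, 3] <- quad_argmax(log(grid), ll, exp = TRUE)
  }
  summary <- data.frame(
    estimator = colnames(out),
    mean = colMeans(out), sd = apply(out, 2, sd),
    se = apply(out, 2, sd) / sqrt(reps))
  list(model = model, summary = summary, per_rep = as.data.frame(out),
       reps = reps)
}

# quadratic interpolation of an argmax over a grid
quad_argmax <- function(x, y, exp = FALSE) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) {
    out <- x[i]
  } else {
    x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
    denom <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
    a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) +
            x3[1] * (y3[3] - y3[2])) / denom
    b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) +
            x3[1]^2 * (y3[2] - y3[3])) / denom
    out <- if (a < 0) -b / (2 * a) else x[i]
    out <- min(max(out, x3[1]), x3[3])
  }
  if (exp) exp(out) else out
}
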