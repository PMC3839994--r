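#' Specify a synthetic haplotype-table scenario
#'
#' Wraps a [demographic_model()] with the bookkeeping needed to emit a
#' full [haplotype_dataset()] with known ground truth: population labels,
#' a seed, nucleotide assignment, synthetic outgroup rows carrying the
#' true ancestral allele (with configurable error), and an optional
#' forced CpG-style recurrent mutation to exercise conflict resolution.
#'
#' @param name scenario name (recorded on the output).
#' @param model a [demographic_model()].
#' @param population_labels one label per deme.
#' @param seed integer seed; `(name, seed)` determines the output exactly.
#' @param outgroup_error per-site probability that a synthetic outgroup
#'   shows the derived instead of the true ancestral allele.
#' @param force_recurrence inject one artificial recurrent mutation at a
#'   CpG-flagged site (creating a four-gamete conflict with known truth).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, model,
                          population_labels = paste0("deme",
                                                     seq_len(model$n_demes)),
                          seed = 1, outgroup_error = 0,
                          force_recurrence = FALSE) {
  stopifnot(length(population_labels) == model$n_demes)
  structure(list(name = name, model = model,
                 population_labels = population_labels, seed = seed,
                 outgroup_error = outgroup_error,
                 force_recurrence = force_recurrence),
            class = "scenario_spec")
}

#' Generate a synthetic haplotype dataset with ground truth
#'
#' Simulates one sample under the scenario's demographic model and dresses
#' it up as a complete [haplotype_dataset()]: random ancestral/derived
#' bases at random positions, three synthetic outgroup rows (chimpanzee,
#' orangutan, macaque) carrying the true simulated ancestral allele
#' (subject to `outgroup_error`), and per-population haplotype counts.
#' With `force_recurrence` one extra derived allele is placed on a
#' haplotype outside an existing mutation's clade, at a CpG-flagged site,
#' so that the four-gamete check must fire exactly there.
#'
#' @param spec a [scenario_spec()].
#' @return A [haplotype_dataset()]; attributes `"truth"` (list with
#'   `tmrca`, `S`, `genealogy`, and if forced, `recurrent_label` and
#'   `recurrent_haplotype`) and `"scenario"`.
#' @export
generate_dataset <- function(spec) {
  set.seed(spec$seed)
  model <- spec$model
  sim <- sim_one(model)
  mat <- sim$matrix
  n <- nrow(mat)
  S <- ncol(mat)
  truth <- list(tmrca = sim$tmrca, S = S, genealogy = sim$genealogy)

  recurrent <- NULL
  if (spec$force_recurrence) {
    if (S < 2) stop("force_recurrence needs at least two segregating sites")
    recurrent <- find_recurrence_slot(mat)
    if (is.null(recurrent))
      stop("no suitable site/haplotype pair for a forced recurrence; ",
           "use a scenario with more variation")
    mat[recurrent$row, recurrent$col] <- 1L
    truth$recurrent_label <- paste0("m", recurrent$col)
  }

  pos <- sort(sample.int(model$segment_length_bp, max(S, 0)))
  anc <- sample(ALLELES, S, replace = TRUE)
  der <- vapply(anc, function(a)
    sample(setdiff(ALLELES, a), 1), "")
  alleles_chr <- matrix(rep(anc, each = n), n, S)
  alleles_chr[mat == 1L] <- matrix(rep(der, each = n), n, S)[mat == 1L]

  # collapse chromosomes into haplotypes with per-population counts
  key <- apply(alleles_chr, 1, paste, collapse = "")
  first <- which(!duplicated(key))
  hap <- alleles_chr[first, , drop = FALSE]
  ids <- paste0("H", seq_along(first))
  counts <- matrix(0L, length(first), model$n_demes)
  for (i in seq_len(n)) {
    r <- match(key[i], key[first])
    counts[r, sim$deme[i]] <- counts[r, sim$deme[i]] + 1L
  }
  rownames(hap) <- rownames(counts) <- ids
  colnames(counts) <- spec$population_labels
  if (spec$force_recurrence)
    truth$recurrent_haplotype <- ids[match(key[recurrent$row], key[first])]

  og_draw <- function() {
    flip <- runif(S) < spec$outgroup_error
    ifelse(flip, der, anc)
  }
  outg <- rbind(chimpanzee = og_draw(), orangutan = og_draw(),
                macaque = og_draw())
  cpg <- rep(FALSE, S)
  if (spec$force_recurrence) cpg[recurrent$col] <- TRUE

  ds <- haplotype_dataset(
    sites = data.frame(position = pos, label = as.character(seq_len(S)),
                       ancestral = anc, cpg = cpg),
    alleles = hap, counts = counts,
    populations = data.frame(name = spec$population_labels,
                             region = "synthetic"),
    outgroups = outg,
    segment_length_bp = model$segment_length_bp,
    reference = "synthetic", chrom = "sim")
  attr(ds, "truth") <- truth
  attr(ds, "scenario") <- spec$name
  ds
}

# find (row, col) such that setting mat[row, col] = 1 creates a
# four-gamete conflict involving col only
find_recurrence_slot <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  dc <- colSums(mat)
  for (col in order(-dc)) {
    if (dc[col] < 2 || dc[col] > n - 2) next
    for (row in which(mat[, col] == 0L)) {
      trial <- mat
      trial[row, col] <- 1L
      conflict <- FALSE
      clean <- TRUE
      for (d in seq_len(S)) {
        if (d == col) next
        g <- unique(trial[, col] * 2L + trial[, d])
        if (length(g) == 4L) conflict <- TRUE
        g0 <- unique(mat[, col] * 2L + mat[, d])
        if (length(g0) == 4L) clean <- FALSE
      }
      if (conflict && clean) return(list(row = row, col = col))
    }
  }
  NULL
}

#' Estimator and dating recovery against simulated ground truth
#'
#' Three self-checks of the pipeline on synthetic data:
#' (1) bias and RMSE of theta_pi and Watterson's theta_S over a grid of
#' true thetas under constant size; (2) coverage of the rho TMRCA
#' estimate (within 2 SD of the truth, in mutation units); (3) the
#' Chakraborty amalgamation probability contrasted between a subdivided
#' and a panmictic scenario.
#'
#' @param theta_grid true thetas for the bias scan.
#' @param n sample size.
#' @param reps replicates per cell.
#' @param seed integer seed.
#' @return list of data.frames `theta_bias`, `rho_coverage`,
#'   `chakraborty_contrast`.
#' @export
recovery_suite <- function(theta_grid = c(2, 5, 10), n = 50, reps = 200,
                           seed = 1) {
  set.seed(seed)
  bias <- lapply(theta_grid, function(th) {
    model <- demographic_model(th, n)
    est <- t(vapply(seq_len(reps), function(i) {
      sim <- sim_one(model)
      bm <- sim_binary_matrix(sim)
      sfs <- unfolded_sfs(bm)
      c(pi = sum(2 * sfs * (n - sfs)) / (n * (n - 1)),
        S = length(sfs) / harmonic1(n))
    }, numeric(2)))
    data.frame(theta = th,
               bias_pi = mean(est[, 1]) - th,
               bias_S = mean(est[, 2]) - th,
               rmse_pi = sqrt(mean((est[, 1] - th)^2)),
               rmse_S = sqrt(mean((est[, 2] - th)^2)),
               se = sd(est[, 2]) / sqrt(reps))
  })
  # rho TMRCA recovery (coalescent-unit scale: rho / (theta/2))
  model <- demographic_model(5, n)
  cov <- vapply(seq_len(reps), function(i) {
    sim <- sim_one(model)
    if (sim$S == 0) return(NA)
    bm <- sim_binary_matrix(sim)
    gt <- build_gene_tree(bm)
    cal <- calibrate_rate()  # any calibration: compare on the unit scale
    a <- rho_age(gt, "root", cal)
    est_units <- a$rho / (model$theta / 2)
    sd_units <- a$sd_rho / (model$theta / 2)
    abs(est_units - sim$tmrca) <= 2 * sd_units
  }, NA)
  rho_cov <- data.frame(coverage_2sd = mean(cov, na.rm = TRUE),
                        reps = sum(!is.na(cov)))
  # Chakraborty contrast: the data-like scenario (ancient subdivision with
  # subsequent growth) pools differentiated lineages and should enrich the
  # amalgamation test for small probabilities relative to panmixia
  pk <- function(model) {
    vapply(seq_len(reps), function(i) {
      sim <- sim_one(model)
      bm <- sim_binary_matrix(sim)
      if (length(unfolded_sfs(bm)) == 0) return(NA_real_)
      th <- theta_estimators(bm)
      if (th$theta_pi <= 0) return(NA_real_)
      d <- ewens_k_distribution(bm$n, th$theta_pi)
      sum(d[nrow(bm$x):bm$n])
    }, 0)
  }
  p_sub <- pk(coalsim_preset("combined_subdivision_growth", n = n))
  p_pan <- pk(coalsim_preset("constant", theta = 7.5, n = n))
  contrast <- data.frame(
    scenario = c("combined_subdivision_growth", "constant"),
    frac_p_below_0.05 = c(mean(p_sub < 0.05, na.rm = TRUE),
                          mean(p_pan < 0.05, na.rm = TRUE)),
    median_p = c(stats::median(p_sub, na.rm = TRUE),
                 stats::median(p_pan, na.rm = TRUE)))
  list(theta_bias = do.call(rbind, bias), rho_coverage = rho_cov,
       chakraborty_contrast = contrast)
}
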