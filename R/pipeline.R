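#' Population name helpers
#'
#' @param ds a [haplotype_dataset()].
#' @return Character vector of population names.
#' @export
african_populations <- function(ds)
  ds$populations$name[ds$populations$region != "non-African"]

#' @rdname african_populations
#' @export
non_african_populations <- function(ds)
  ds$populations$name[ds$populations$region == "non-African"]

#' Binary matrix for a population subset plus named extra chromosomes
#'
#' Convenience around [as_binary_matrix()] for samples like "all
#' sub-Saharan Africans plus one named non-African chromosome": the
#' `extra` argument adds chromosomes of given haplotypes on top of the
#' population selection.
#'
#' @param ds a polarized [haplotype_dataset()].
#' @param populations population names (default: all).
#' @param extra named integer vector: haplotype id -> additional copies.
#' @return A `binary_matrix`.
#' @export
sample_binary_matrix <- function(ds, populations = NULL, extra = NULL) {
  if (is.null(extra) || !length(extra))
    return(as_binary_matrix(ds, populations))
  bad <- setdiff(names(extra), rownames(ds$alleles))
  if (length(bad)) stop("unknown haplotypes in extra: ",
                        paste(bad, collapse = ", "))
  # add a pseudo-population holding the extra chromosomes
  ds2 <- ds
  add <- integer(nrow(ds$counts))
  add[match(names(extra), rownames(ds$counts))] <- as.integer(extra)
  ds2$counts <- cbind(ds$counts, ".extra" = add)
  ds2$populations <- rbind(ds$populations,
                           data.frame(name = ".extra", region = "extra"))
  pn <- if (is.null(populations)) ds$populations$name else populations
  bm <- as_binary_matrix(ds2, c(pn, ".extra"))
  bm$populations <- setdiff(bm$populations, ".extra")
  bm
}

#' Haplotype and clade frequencies within a population subset
#'
#' @param ds a [haplotype_dataset()].
#' @param haplotypes haplotype ids forming the clade of interest.
#' @param populations populations defining the denominator sample.
#' @return list with `count`, `n`, `frequency`.
#' @export
clade_frequency <- function(ds, haplotypes, populations = NULL) {
  pn <- ds$populations$name
  if (is.null(populations)) populations <- pn
  cols <- match(populations, pn)
  if (anyNA(cols)) stop("unknown populations")
  n <- sum(ds$counts[, cols])
  cnt <- sum(ds$counts[haplotypes, cols])
  list(count = cnt, n = n, frequency = cnt / n)
}

# haplotypes carrying a given mutation label (clade below that mutation)
haplotypes_with_mutation <- function(ds, label) {
  bm <- as_binary_matrix(ds)
  j <- match(label, bm$labels)
  if (is.na(j)) stop("unknown mutation label ", label)
  bm$haplotype_id[!is.na(bm$x[, j]) & bm$x[, j] == 1L]
}

#' Run the complete single-locus analysis
#'
#' Orchestrates load -> polarization check -> statistics per grouping ->
#' recurrence resolution -> gene tree -> rho dating -> (optionally)
#' Griffiths-Tavare likelihood fits, on the dataset's standard groupings:
#' each population, all sub-Saharan Africans, non-Africans, the pooled
#' total, and the tree sample (sub-Saharan plus any `extra_chromosomes`).
#'
#' @param ds a polarized [haplotype_dataset()] (default: the bundled
#'   MTMR8 table).
#' @param cal a [calibrate_rate()] object.
#' @param extra_chromosomes named vector of haplotype -> copies appended
#'   to the sub-Saharan sample for tree building and dating (default: the
#'   single Lebanese H23 chromosome, following the source analysis).
#' @param reps Monte-Carlo replicates for test p-values.
#' @param seed integer seed.
#' @param genetree logical: also run the constant-size and growth-model
#'   maximum-likelihood fits and coalescent ages (slow).
#' @param budget IS histories per grid point for the genetree stage.
#' @param output_dir if non-NULL, write JSON and TSV reports there.
#' @return list with `diversity` (per-grouping [neutrality_report()]s),
#'   `frequencies`, `tree`, `rho_table`, and (if `genetree`)
#'   `ml_constant`, `ml_growth`, `genetree_ages`.
#' @export
run_full_analysis <- function(ds = mtmr8_dataset(),
                              cal = calibrate_rate(),
                              extra_chromosomes = c(H23 = 1),
                              reps = 10000, seed = 1,
                              genetree = FALSE, budget = 1e5,
                              output_dir = NULL) {
  afr <- african_populations(ds)
  nonafr <- non_african_populations(ds)
  groupings <- list(total = ds$populations$name)
  if (length(afr)) groupings$sub_saharan <- afr
  if (length(nonafr)) groupings$non_african <- nonafr
  for (p in ds$populations$name) groupings[[p]] <- p

  diversity <- lapply(groupings, function(pops) {
    bm <- as_binary_matrix(ds, pops)
    if (bm$n < 2) return(NULL)
    neutrality_report(bm, reps = reps, seed = seed)
  })

  # headline clade frequencies
  frequencies <- list(
    k_total = nrow(ds$alleles),
    k_by_grouping = lapply(groupings, function(pops)
      sum(rowSums(ds$counts[, match(pops, ds$populations$name),
                            drop = FALSE]) > 0))
  )

  bm_tree <- sample_binary_matrix(ds, if (length(afr)) afr else NULL,
                                  extra = extra_chromosomes)
  bm_res <- resolve_recurrences(bm_tree)
  gt <- build_gene_tree(bm_res)
  rho_table <- rho_age_table(gt, cal, rate_uncertainty = TRUE)

  out <- list(dataset = ds, groupings = groupings, diversity = diversity,
              frequencies = frequencies, tree = gt, rho_table = rho_table,
              calibration = cal, seed = seed, reps = reps)

  if (genetree) {
    th0 <- theta_estimators(bm_tree)
    grid <- seq(max(1, th0$theta_S * 0.6), th0$theta_S * 2.2,
                length.out = 15)
    mlc <- likelihood_surface(gt, "constant", theta_grid = grid,
                              budget = budget, seed = seed)
    mlg <- profile_growth_search(gt, mlc$theta_ml, budget = budget,
                                 seed = seed)
    ages <- estimate_ages(gt, mlg$theta_ml, mlg$beta_ml,
                          budget = budget, seed = seed, cal = cal)
    out$ml_constant <- mlc
    out$ml_growth <- mlg
    out$genetree_ages <- ages
  }

  if (!is.null(output_dir)) write_analysis_reports(out, output_dir)
  out
}

# flatten a neutrality_report into one named row
report_row <- function(r) {
  data.frame(
    n = r$n, k = r$k, S = r$S,
    theta_pi = r$theta$theta_pi, theta_S = r$theta$theta_S,
    theta_H = r$theta$theta_H, theta_k = r$theta$theta_k,
    theta_G = r$theta$theta_G, pi_bp = r$theta$pi_bp,
    homozygosity = r$homozygosity,
    ew_expected_hom = r$ewens$expected_homozygosity,
    watterson_p = r$ewens$watterson_p, slatkin_p = r$ewens$slatkin_p,
    chakraborty_k_exp = r$ewens$chakraborty$k_exp,
    chakraborty_p = r$ewens$chakraborty$p_k_or_more,
    tajima_D = r$tajima$D, tajima_p = r$tajima$p,
    fu_fs = r$fu$Fs, fu_p = r$fu$p,
    fay_wu_H = r$fay_wu$H, fay_wu_H_norm = r$fay_wu$H_normalized,
    fay_wu_p = r$fay_wu$p)
}

#' Write JSON and TSV reports for a full analysis
#'
#' Emits `diversity.tsv` / `diversity.json` (one row/record per
#' grouping, mirroring a diversity-and-neutrality table), `dating.tsv`
#' (the rho table), and `run.json` (seeds, replicate counts,
#' calibration).  No multiple-testing adjustment is applied; p-values are
#' reported raw.
#'
#' @param res result of [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @export
write_analysis_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(res$diversity), function(g) {
    r <- res$diversity[[g]]
    if (is.null(r)) return(NULL)
    cbind(grouping = g, report_row(r))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(dir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, file.path(dir, "diversity.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write.table(res$rho_table, file.path(dir, "dating.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(seed = res$seed, reps = res$reps,
               calibration = unclass(res$calibration),
               note = "p-values are raw; no multiple-testing adjustment")
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$genetree_ages)) {
    write.table(res$genetree_ages$ages, file.path(dir, "genetree_ages.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
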