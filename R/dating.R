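#' Calibrate the per-segment mutation rate from interspecies divergence
#'
#' The per-generation substitution rate of the segment is
#' `divergence_per_bp * L * generation_years / (2 * split_time_years)`
#' (the factor 2 accounts for the two lineages since the species split).
#' The optional male/female mutation-rate ratio `alpha` yields the
#' autosomal-equivalent rate via the X-to-autosome factor
#' `3(alpha+1) / (2(alpha+2))`.
#'
#' @param divergence_per_bp substitutions per site between the in-group and
#'   the calibrating outgroup (human-chimpanzee here).
#' @param divergence_sd standard deviation of `divergence_per_bp`
#'   (propagated into optional rate-uncertainty bands).
#' @param L segment length in bp.
#' @param split_time_years species separation time in years.
#' @param generation_years average generation time along both lineages.
#' @param alpha optional male/female mutation-rate ratio.
#' @return Object of class `rate_calibration` with `mu_segment`
#'   (per segment per generation), `mu_bp`, `mu_rel_sd`, and (if `alpha`
#'   given) `mu_bp_autosomal`.
#' @export
calibrate_rate <- function(divergence_per_bp = 0.0081,
                           L = 11024,
                           split_time_years = 7.5e6,
                           generation_years = 25,
                           alpha = NULL,
                           divergence_sd = 0.0009) {
  stopifnot(divergence_per_bp >= 0, L > 0, split_time_years > 0,
            generation_years > 0)
  generations_since_split <- 2 * split_time_years / generation_years
  mu_bp <- divergence_per_bp / generations_since_split
  mu_segment <- mu_bp * L
  out <- list(divergence_per_bp = divergence_per_bp,
              divergence_sd = divergence_sd,
              segment_length_bp = L,
              split_time_years = split_time_years,
              generation_years = generation_years,
              alpha = alpha,
              mu_segment = mu_segment,
              mu_bp = mu_bp,
              mu_rel_sd = if (divergence_per_bp > 0)
                divergence_sd / divergence_per_bp else NA_real_)
  if (!is.null(alpha))
    out$mu_bp_autosomal <- mu_bp * 3 * (alpha + 1) / (2 * (alpha + 2))
  structure(out, class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat(sprintf("mu = %.3g / segment / generation (%.3g / bp), %d bp segment\n",
              x$mu_segment, x$mu_bp, x$segment_length_bp))
  cat(sprintf("calibration: %.4g subst/bp over %.3g y split, %g y/generation\n",
              x$divergence_per_bp, x$split_time_years, x$generation_years))
  if (!is.null(x$alpha))
    cat(sprintf("autosomal-equivalent mu/bp (alpha = %.2f): %.3g\n",
                x$alpha, x$mu_bp_autosomal))
  invisible(x)
}

# nodes in the subtree rooted at v (excluding v itself)
subtree_nodes <- function(gt, v) {
  V <- length(gt$parent)
  inside <- logical(V)
  inside[v] <- TRUE
  for (u in seq_len(V)) {      # parents precede children by construction
    p <- gt$parent[u]
    if (p > 0 && inside[p]) inside[u] <- TRUE
  }
  which(inside & seq_len(V) != v)
}

#' Date a node or mutation of a gene tree by the rho statistic
#'
#' rho is the average number of mutations from the focal ancestral node to
#' its sampled descendants; its standard deviation follows Saillard:
#' `sd(rho) = sqrt(sum over branches below of (n_b / n)^2 m_b)`.  Age in
#' generations is `rho / mu_segment`, in years times `generation_years`.
#'
#' The focal point for a mutation label is the point on the tree
#' immediately below that mutation; other mutations on the same branch
#' that are stored below it (ascending reference position, flagged
#' order-arbitrary) count towards the descendant paths.
#'
#' @param gt a `gene_tree`.
#' @param focal `"root"`, a mutation label, or a node index.
#' @param cal a [calibrate_rate()] object.
#' @param rate_uncertainty also fold the calibration's relative rate SD
#'   into a second, wider SD (`sd_years_with_rate`).
#' @return Object of class `age_estimate`: `rho`, `sd_rho`, `n_sub`,
#'   `generations`, `sd_generations`, `years`, `sd_years`, and
#'   `sd_years_with_rate` if requested.
#' @export
rho_age <- function(gt, focal = "root", cal = calibrate_rate(),
                    rate_uncertainty = FALSE) {
  v <- if (identical(focal, "root")) 1L
       else if (is.character(focal)) mutation_node(gt, focal)
       else as.integer(focal)
  if (gt$n_sub[v] < 1) stop("focal node subtends no sampled chromosomes")
  below <- subtree_nodes(gt, v)
  nsub <- gt$n_sub[v]
  rho <- sum(gt$n_sub[below]) / nsub
  sd_rho <- sqrt(sum((gt$n_sub[below] / nsub)^2))
  gens <- if (cal$mu_segment > 0) rho / cal$mu_segment else NA_real_
  sdg <- if (cal$mu_segment > 0) sd_rho / cal$mu_segment else NA_real_
  out <- list(focal = focal, node = v, n_sub = nsub,
              rho = rho, sd_rho = sd_rho,
              generations = gens, sd_generations = sdg,
              years = gens * cal$generation_years,
              sd_years = sdg * cal$generation_years,
              method = "rho",
              order_arbitrary = isTRUE(gt$order_arbitrary[v]),
              undefined_rate = cal$mu_segment <= 0)
  if (rate_uncertainty && rho > 0 && !is.na(cal$mu_rel_sd))
    out$sd_years_with_rate <- out$years *
      sqrt((sd_rho / rho)^2 + cal$mu_rel_sd^2)
  structure(out, class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("%s dating of %s: rho = %.4g +/- %.4g (n_sub = %d)\n",
              x$method, paste(x$focal, collapse = ","), x$rho, x$sd_rho,
              x$n_sub))
  if (isTRUE(x$undefined_rate)) cat("  mutation rate is zero: age undefined\n")
  else cat(sprintf("  %.0f +/- %.0f generations = %.1f +/- %.1f Ky\n",
                   x$generations, x$sd_generations, x$years / 1000,
                   x$sd_years / 1000))
  if (isTRUE(x$order_arbitrary))
    cat("  note: mutation shares its branch; within-branch order is arbitrary\n")
  invisible(x)
}

#' rho-statistic ages for a set of mutations plus the TMRCA
#'
#' @param gt a `gene_tree`.
#' @param cal a [calibrate_rate()] object.
#' @param mutations mutation labels to date (default: all).
#' @param rate_uncertainty see [rho_age()].
#' @return data.frame, one row per focal point (TMRCA first), with rho,
#'   SDs, generations and years.
#' @export
rho_age_table <- function(gt, cal = calibrate_rate(), mutations = NULL,
                          rate_uncertainty = FALSE) {
  if (is.null(mutations))
    mutations <- gt$mutation[!is.na(gt$mutation)]
  focals <- c("root", mutations)
  rows <- lapply(focals, function(f) {
    a <- rho_age(gt, f, cal, rate_uncertainty)
    data.frame(focal = if (identical(f, "root")) "TMRCA" else f,
               n_sub = a$n_sub, rho = a$rho, sd_rho = a$sd_rho,
               generations = a$generations,
               years_ky = a$years / 1000, sd_years_ky = a$sd_years / 1000,
               sd_years_with_rate_ky = if (rate_uncertainty &&
                                           !is.null(a$sd_years_with_rate))
                 a$sd_years_with_rate / 1000 else NA_real_,
               order_arbitrary = a$order_arbitrary)
  })
  do.call(rbind, rows)
}
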