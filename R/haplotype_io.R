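#' @useDynLib xhaplo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot rexp runif rpois optimize setNames sd var
#' @importFrom utils read.table write.table head tail
"_PACKAGE"

ALLELES <- c("A", "C", "G", "T")

#' Construct a haplotype dataset for a single non-recombining segment
#'
#' A `haplotype_dataset` holds the complete observed variation of one locus:
#' the ordered polymorphic sites (reference coordinates, mutation labels,
#' ancestral state, CpG flag), the distinct haplotypes as allele vectors over
#' those sites, per-population counts of each haplotype, and the outgroup /
#' archaic alleles used for polarization.
#'
#' Sites that belong to one mutational event (adjacent positions that always
#' co-segregate and are interpreted as a single mutation) share a `label`;
#' all statistics and tree operations treat such an event group as one
#' mutation.
#'
#' @param sites data.frame with columns `position` (1-based on `reference`),
#'   `label` (mutation label, shared within an event group), `ancestral`
#'   (base or NA if not yet polarized), `cpg` (logical hypermutability flag).
#' @param alleles character matrix, haplotypes x sites, of observed bases.
#' @param counts integer matrix, haplotypes x populations.
#' @param populations data.frame with columns `name` and `region`
#'   (one of `"south"`, `"west-central"`, `"east"`, `"non-African"`).
#' @param outgroups character matrix, outgroups x sites (rownames name the
#'   outgroup; `NA` = missing).  The first row should be the closest
#'   outgroup (chimpanzee) for the polarization rule.
#' @param archaics optional character matrix like `outgroups` (annotation
#'   only; never used to polarize).
#' @param segment_length_bp total resequenced length in bp (monomorphic
#'   positions included); used to express diversity per bp.
#' @param reference,chrom reference build and chromosome names.
#' @return An object of class `haplotype_dataset`.
#' @export
haplotype_dataset <- function(sites, alleles, counts, populations,
                              outgroups = NULL, archaics = NULL,
                              segment_length_bp, reference = "unknown",
                              chrom = "X") {
  sites <- as.data.frame(sites)
  stopifnot(all(c("position", "label", "ancestral", "cpg") %in% names(sites)))
  alleles <- as.matrix(alleles)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  ds <- structure(list(
    sites = sites, alleles = alleles, counts = counts,
    populations = as.data.frame(populations),
    outgroups = outgroups, archaics = archaics,
    segment_length_bp = as.integer(segment_length_bp),
    reference = reference, chrom = chrom
  ), class = "haplotype_dataset")
  validate_haplotype_dataset(ds)
  ds
}

validate_haplotype_dataset <- function(ds) {
  s <- ds$sites
  if (anyDuplicated(s$position))
    stop("duplicated site positions: ",
         paste(s$position[duplicated(s$position)], collapse = ", "))
  if (is.unsorted(s$position))
    stop("sites must be ordered by position")
  ok <- matrix(ds$alleles %in% ALLELES | is.na(ds$alleles),
               nrow(ds$alleles))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("invalid allele symbol in haplotype row %d, site column %d",
                 bad[1], bad[2]))
  }
  if (any(ds$counts < 0, na.rm = TRUE))
    stop("negative haplotype counts")
  if (nrow(ds$counts) != nrow(ds$alleles))
    stop("counts and alleles disagree on the number of haplotypes")
  if (ncol(ds$counts) != nrow(ds$populations))
    stop("counts and populations disagree on the number of populations")
  pol <- !is.na(s$ancestral)
  if (any(pol)) {
    # each polarized site carries at most one derived base
    for (j in which(pol)) {
      obs <- unique(ds$alleles[, j])
      obs <- obs[!is.na(obs)]
      if (!s$ancestral[j] %in% c(obs, ALLELES))
        stop("ancestral state at position ", s$position[j],
             " is not a valid base")
      if (length(setdiff(obs, s$ancestral[j])) > 1)
        stop("site at position ", s$position[j],
             " has more than one derived allele")
    }
  }
  invisible(ds)
}

n_chromosomes <- function(ds) sum(ds$counts)

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf(
    "haplotype_dataset: %d haplotypes, %d sites (%d mutation events), %d chromosomes\n",
    nrow(x$alleles), nrow(x$sites), length(unique(x$sites$label)),
    sum(x$counts)))
  cat(sprintf("  %s %s, segment %d bp, populations: %s\n",
              x$reference, x$chrom, x$segment_length_bp,
              paste(x$populations$name, collapse = ", ")))
  invisible(x)
}

#' Read a haplotype table in the native TSV dialect
#'
#' The dialect is UTF-8 TSV.  An optional `##` metadata line
#' (`key=value` fields) is followed by a four-line site header (`position`,
#' `label`, `ancestral`, `cpg`), optional `@<outgroup>` allele rows
#' (`.` = same as the ancestral line, `N` = missing; `@neandertal` and
#' `@denisova` are stored as archaic annotations, any other name as a
#' polarization outgroup), a `populations` line (`name:region` fields), and
#' one row per haplotype: id, one allele field per site (`.` = ancestral),
#' a literal `|`, then one count per population.
#'
#' @param path file path.
#' @return A [haplotype_dataset()].
#' @export
read_haplotype_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  meta <- list(reference = "unknown", chrom = "X", segment_length_bp = NA)
  if (startsWith(lines[1], "##")) {
    for (f in strsplit(lines[1], "\t")[[1]]) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    }
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t")
  tag <- vapply(fields, `[`, "", 1)
  get_row <- function(name) {
    i <- match(name, tag)
    if (is.na(i)) stop("missing header line '", name, "' in ", path)
    fields[[i]][-1]
  }
  position <- suppressWarnings(as.integer(get_row("position")))
  if (anyNA(position)) stop("non-numeric position in site header")
  S <- length(position)
  label <- get_row("label")
  anc <- get_row("ancestral")
  anc[anc %in% c(".", "N", "?")] <- NA
  cpg <- get_row("cpg") == "1"
  if (length(label) != S || length(anc) != S || length(cpg) != S)
    stop("site header lines have unequal lengths")
  sites <- data.frame(position = position, label = label,
                      ancestral = anc, cpg = cpg)

  expand_og <- function(v) {
    v[v %in% c("N", "?", "")] <- NA
    dot <- !is.na(v) & v == "."
    v[dot] <- anc[dot]
    v
  }
  og_idx <- grep("^@", tag)
  outg <- NULL; arch <- NULL
  for (i in og_idx) {
    nm <- sub("^@", "", tag[i])
    v <- expand_og(fields[[i]][-1])
    if (length(v) != S) stop("outgroup row @", nm, " has wrong length")
    if (nm %in% c("neandertal", "denisova"))
      arch <- rbind(arch, setNames(matrix(v, 1), NULL))
    else
      outg <- rbind(outg, matrix(v, 1))
    if (nm %in% c("neandertal", "denisova"))
      rownames(arch)[nrow(arch)] <- nm
    else rownames(outg)[nrow(outg)] <- nm
  }

  pop_f <- get_row("populations")
  pp <- strsplit(pop_f, ":", fixed = TRUE)
  populations <- data.frame(name = vapply(pp, `[`, "", 1),
                            region = vapply(pp, `[`, "", 2))
  P <- nrow(populations)

  hap_i <- which(!tag %in% c("position", "label", "ancestral", "cpg",
                             "populations") & !startsWith(tag, "@"))
  alleles <- matrix(NA_character_, length(hap_i), S)
  counts <- matrix(0L, length(hap_i), P)
  ids <- character(length(hap_i))
  for (r in seq_along(hap_i)) {
    f <- fields[[hap_i[r]]]
    ids[r] <- f[1]
    bar <- match("|", f)
    if (is.na(bar) || bar != S + 2)
      stop("haplotype row '", f[1], "': expected ", S,
           " allele fields before '|'")
    al <- f[2:(S + 1)]
    al[al == "."] <- anc[al == "."]
    al[al %in% c("N", "?")] <- NA
    alleles[r, ] <- al
    cn <- suppressWarnings(as.integer(f[(bar + 1):(bar + P)]))
    if (anyNA(cn)) stop("haplotype row '", f[1], "': bad count field")
    counts[r, ] <- cn
  }
  rownames(alleles) <- rownames(counts) <- ids
  colnames(counts) <- populations$name

  haplotype_dataset(sites, alleles, counts, populations,
                    outgroups = outg, archaics = arch,
                    segment_length_bp = as.integer(meta$segment_length_bp),
                    reference = meta$reference, chrom = meta$chrom)
}

#' Write a haplotype dataset in the native TSV dialect
#'
#' Inverse of [read_haplotype_table()]; a write/read round trip reproduces
#' positions, labels, allele states and counts exactly.
#'
#' @param ds a [haplotype_dataset()].
#' @param path output file path.
#' @export
write_haplotype_table <- function(ds, path) {
  s <- ds$sites
  anc <- s$ancestral
  ln <- c(sprintf("## xhaplo haplotype table v1\treference=%s\tchrom=%s\tsegment_length_bp=%d",
                  ds$reference, ds$chrom, ds$segment_length_bp),
          paste(c("position", s$position), collapse = "\t"),
          paste(c("label", s$label), collapse = "\t"),
          paste(c("ancestral", ifelse(is.na(anc), ".", anc)), collapse = "\t"),
          paste(c("cpg", as.integer(s$cpg)), collapse = "\t"))
  fmt_og <- function(v) {
    out <- ifelse(is.na(v), "N", ifelse(!is.na(anc) & v == anc, ".", v))
    out
  }
  for (m in list(ds$outgroups, ds$archaics))
    if (!is.null(m))
      for (r in seq_len(nrow(m)))
        ln <- c(ln, paste(c(paste0("@", rownames(m)[r]), fmt_og(m[r, ])),
                          collapse = "\t"))
  ln <- c(ln, paste(c("populations",
                      paste0(ds$populations$name, ":", ds$populations$region)),
                    collapse = "\t"))
  for (r in seq_len(nrow(ds$alleles))) {
    al <- ds$alleles[r, ]
    al <- ifelse(is.na(al), "N", ifelse(!is.na(anc) & al == anc, ".", al))
    ln <- c(ln, paste(c(rownames(ds$alleles)[r], al, "|", ds$counts[r, ]),
                      collapse = "\t"))
  }
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

#' Load the bundled MTMR8-region haplotype table
#'
#' An 11,024-bp low-recombination segment of the X-linked MTMR8 gene typed
#' in 160 chromosomes (111 sub-Saharan African in eight populations, 49
#' non-African): 24 distinct haplotypes over 37 polymorphic positions
#' (GRCh37), with chimpanzee-polarized ancestral alleles and
#' Neandertal/Denisova annotations.  The adjacent positions
#' 63565561/63565562 always co-segregate and are labelled as the single
#' mutational event `1-2`.
#'
#' @return A [haplotype_dataset()].
#' @export
mtmr8_dataset <- function() {
  read_haplotype_table(system.file("extdata", "mtmr8_haplotypes.tsv",
                                   package = "xhaplo", mustWork = TRUE))
}

#' Infer ancestral alleles from outgroup sequences
#'
#' A human allele identical by state with the chimpanzee allele is taken as
#' ancestral; where the chimpanzee state is missing or does not match any
#' human allele, agreement of at least two other outgroups with a human
#' allele is required.  Sites satisfying neither rule are flagged
#' unresolved (ancestral = NA) and are excluded from polarized statistics.
#'
#' @param ds a [haplotype_dataset()] with an `outgroups` matrix whose first
#'   row is the closest outgroup (chimpanzee).
#' @return `ds` with `sites$ancestral` replaced by the inferred states; the
#'   integer vector of unresolved site indices is attached as attribute
#'   `"unresolved"`.
#' @export
infer_ancestral_alleles <- function(ds) {
  og <- ds$outgroups
  if (is.null(og)) stop("dataset has no outgroup alleles")
  S <- nrow(ds$sites)
  anc <- rep(NA_character_, S)
  for (j in seq_len(S)) {
    human <- unique(ds$alleles[, j])
    human <- human[!is.na(human)]
    anc[j] <- ancestral_rule(human, chimp = og[1, j],
                             others = if (nrow(og) > 1) og[-1, j] else
                               character())
  }
  unresolved <- which(is.na(anc))
  ds$sites$ancestral <- anc
  validate_haplotype_dataset(ds)
  attr(ds, "unresolved") <- unresolved
  ds
}

#' Ancestral-allele decision rule for one site
#'
#' @param human character vector of observed human alleles at the site.
#' @param chimp chimpanzee allele (NA if missing).
#' @param others alleles of the remaining outgroups (NA allowed).
#' @return The ancestral base, or NA if unresolved.
#' @export
ancestral_rule <- function(human, chimp, others = character()) {
  if (!is.na(chimp) && chimp %in% human) return(chimp)
  others <- others[!is.na(others)]
  if (length(others) >= 2) {
    tab <- table(others[others %in% human])
    hit <- names(tab)[tab >= 2]
    if (length(hit) == 1) return(hit)
  }
  NA_character_
}

#' Encode a haplotype dataset as a polarized binary matrix
#'
#' Rows are distinct haplotypes (with multiplicities), columns are mutation
#' events: sites sharing an event-group `label` are collapsed into a single
#' column (their 0/1 patterns must agree).  Entries are 0 (ancestral),
#' 1 (derived) or NA (missing).  Columns monomorphic within the selected
#' populations are retained and flagged via the `segregating` element.
#'
#' @param ds a polarized [haplotype_dataset()].
#' @param populations character vector of population names to keep
#'   (default: all).  Haplotypes absent from the selection are dropped.
#' @return An object of class `binary_matrix`: list with elements `x`
#'   (0/1/NA integer matrix), `counts` (chromosomes per row), `labels`,
#'   `positions` (first position of each event), `cpg`, `segregating`,
#'   `n` (total chromosomes), `segment_length_bp`.
#' @export
as_binary_matrix <- function(ds, populations = NULL) {
  if (anyNA(ds$sites$ancestral)) {
    bad <- ds$sites$position[is.na(ds$sites$ancestral)]
    stop("unpolarized sites at positions: ", paste(bad, collapse = ", "))
  }
  pn <- ds$populations$name
  if (is.null(populations)) populations <- pn
  miss <- setdiff(populations, pn)
  if (length(miss)) stop("unknown populations: ", paste(miss, collapse = ", "))
  cnt <- rowSums(ds$counts[, match(populations, pn), drop = FALSE])
  if (sum(cnt) == 0) stop("empty sample: selected populations have no chromosomes")
  keep <- cnt > 0

  anc <- ds$sites$ancestral
  bin01 <- t(apply(ds$alleles, 1, function(a) {
    ifelse(is.na(a), NA_integer_, as.integer(a != anc))
  }))
  # collapse event groups (shared labels) into single mutation columns
  lab <- ds$sites$label
  grp <- match(lab, unique(lab))
  x <- matrix(NA_integer_, nrow(bin01), length(unique(lab)))
  pos <- integer(ncol(x)); cpg <- logical(ncol(x))
  for (g in seq_len(ncol(x))) {
    js <- which(grp == g)
    sub <- bin01[, js, drop = FALSE]
    if (length(js) > 1 &&
        any(apply(sub, 1, function(r) length(unique(r[!is.na(r)])) > 1)))
      stop("event group '", unique(lab)[g],
           "' has discordant states within a haplotype")
    x[, g] <- apply(sub, 1, function(r)
      if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE))
    pos[g] <- ds$sites$position[js[1]]
    cpg[g] <- any(ds$sites$cpg[js])
  }
  colnames(x) <- unique(lab)
  x <- x[keep, , drop = FALSE]
  cnt <- cnt[keep]
  n <- sum(cnt)
  dc <- derived_counts(x, cnt)
  structure(list(
    x = x, counts = as.integer(cnt), haplotype_id = rownames(ds$alleles)[keep],
    labels = unique(lab), positions = pos, cpg = cpg,
    segregating = dc > 0 & dc < n, n = n,
    segment_length_bp = ds$segment_length_bp,
    populations = populations
  ), class = "binary_matrix")
}

derived_counts <- function(x, counts) {
  as.integer(colSums(sweep(replace(x, is.na(x), 0L), 1, counts, `*`)))
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d haplotypes (n = %d chromosomes), %d mutation columns (%d segregating)\n",
              nrow(x$x), x$n, ncol(x$x), sum(x$segregating)))
  invisible(x)
}

#' Expand a binary matrix to one row per chromosome
#'
#' @param bm a `binary_matrix`.
#' @return Integer matrix with `bm$n` rows.
#' @export
expand_binary_matrix <- function(bm) {
  out <- bm$x[rep(seq_len(nrow(bm$x)), bm$counts), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a haplotype dataset as minimal VCF 4.2
#'
#' One haploid pseudo-sample per chromosome (named `<population>_<i>`),
#' REF = ancestral allele, ALT = derived, `INFO/AA` = ancestral.
#'
#' @param ds polarized [haplotype_dataset()].
#' @param path output path.
#' @export
write_vcf <- function(ds, path) {
  if (anyNA(ds$sites$ancestral)) stop("polarize the dataset first")
  s <- ds$sites
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", ds$reference),
           sprintf("##contig=<ID=%s>", ds$chrom),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  reps <- rep(seq_len(nrow(ds$counts)), rowSums(ds$counts))
  popof <- unlist(lapply(seq_len(nrow(ds$counts)), function(r)
    rep(ds$populations$name, ds$counts[r, ])))
  sample_names <- paste0(popof, "_", stats::ave(seq_along(reps), popof,
                                                FUN = seq_along))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names)
  rows <- character(nrow(s))
  for (j in seq_len(nrow(s))) {
    anc <- s$ancestral[j]
    obs <- ds$alleles[reps, j]
    der <- setdiff(unique(obs[!is.na(obs)]), anc)
    alt <- if (length(der)) der else "."
    gt <- ifelse(is.na(obs), ".", ifelse(obs == anc, "0", "1"))
    rows[j] <- paste(c(ds$chrom, s$position[j], s$label[j], anc, alt, ".",
                       "PASS", paste0("AA=", anc), "GT", gt),
                     collapse = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Export haplotype sequences over the polymorphic positions as FASTA
#'
#' @param ds a [haplotype_dataset()].
#' @param path output path.
#' @param by `"haplotype"` (one record per distinct haplotype, count in the
#'   header) or `"chromosome"` (one record per chromosome).
#' @export
write_fasta <- function(ds, path, by = c("haplotype", "chromosome")) {
  by <- match.arg(by)
  al <- ds$alleles
  al[is.na(al)] <- "N"
  if (by == "haplotype") {
    nm <- sprintf("%s count=%d", rownames(al), rowSums(ds$counts))
    seqs <- al
  } else {
    reps <- rep(seq_len(nrow(al)), rowSums(ds$counts))
    seqs <- al[reps, , drop = FALSE]
    nm <- paste0(rownames(al)[reps], "_", seq_along(reps))
  }
  dna <- ape::as.DNAbin(seqs)
  rownames(dna) <- nm
  ape::write.FASTA(dna, path)
  invisible(path)
}
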