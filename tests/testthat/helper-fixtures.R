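# shared test constructors ------------------------------------------------

# binary_matrix straight from a 0/1 matrix (rows = haplotypes)
toy_binary_matrix <- function(x, counts = rep(1L, nrow(x)),
                              cpg = rep(FALSE, ncol(x)),
                              positions = seq_len(ncol(x)),
                              labels = as.character(seq_len(ncol(x))),
                              segment_length_bp = 1000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  colnames(x) <- labels
  n <- sum(counts)
  dc <- xhaplo:::derived_counts(x, counts)
  structure(list(x = x, counts = as.integer(counts),
                 haplotype_id = paste0("H", seq_len(nrow(x))),
                 labels = labels, positions = positions, cpg = cpg,
                 segregating = dc > 0 & dc < n, n = n,
                 segment_length_bp = segment_length_bp,
                 populations = "toy"),
            class = "binary_matrix")
}

# gene tree for n = 2: one lineage carries s private mutations
chain_tree <- function(s, mult_tip = 1L, mult_root = 1L) {
  if (s == 0) {
    parent <- 0L
    tm <- mult_root + mult_tip
  } else {
    parent <- c(0L, seq_len(s))
    tm <- c(mult_root, rep(0L, s - 1L), mult_tip)
  }
  tm <- as.integer(tm)
  n_sub <- tm
  for (v in rev(seq_along(parent)[-1]))
    n_sub[parent[v]] <- n_sub[parent[v]] + n_sub[v]
  structure(list(parent = parent,
                 mutation = c(NA_character_,
                              as.character(seq_len(max(s, 0))))[
                                seq_along(parent)],
                 position = seq_along(parent),
                 tip_mult = tm, tip_hap = NA_character_,
                 n_sub = n_sub, n = sum(tm),
                 order_arbitrary = rep(FALSE, length(parent))),
            class = "gene_tree")
}

# mean pairwise Hamming distance over expanded chromosomes (oracle)
allpairs_pi <- function(bm) {
  m <- expand_binary_matrix(bm)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ], na.rm = TRUE)
  tot / (n * (n - 1) / 2)
}

# simulated infinite-sites binary matrix (always a perfect phylogeny)
random_pp_matrix <- function(n, theta, seed) {
  set.seed(seed)
  sim <- xhaplo:::sim_one(demographic_model(theta, n))
  sim_binary_matrix(sim)
}

fixture_ds <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- mtmr8_dataset()
    ds
  }
})

AFR <- function() african_populations(fixture_ds())
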