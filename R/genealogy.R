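#' Four-gamete compatibility test
#'
#' Two polarized binary sites are incompatible with a single mutational
#' history (infinite-sites model) if all four gametes 00, 01, 10, 11 occur.
#' Missing entries are skipped pairwise.
#'
#' @param bm a `binary_matrix` (see [as_binary_matrix()]).
#' @return An `incompatibility_report`: list with `pairs` (data.frame of
#'   violating label pairs) and `per_site` (named violation counts).
#'   The report is empty iff the matrix admits a perfect phylogeny.
#' @export
four_gamete_check <- function(bm) {
  x <- bm$x
  seg <- which(bm$segregating)
  pairs <- list()
  for (a in seq_along(seg)) for (b in seq_len(a - 1L)) {
    i <- seg[a]; j <- seg[b]
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    g <- unique(x[ok, i] * 2L + x[ok, j])
    if (length(g) == 4L)
      pairs[[length(pairs) + 1L]] <- c(bm$labels[j], bm$labels[i])
  }
  pairs <- if (length(pairs))
    data.frame(site1 = vapply(pairs, `[`, "", 1),
               site2 = vapply(pairs, `[`, "", 2))
  else data.frame(site1 = character(), site2 = character())
  per_site <- table(factor(c(pairs$site1, pairs$site2), levels = bm$labels))
  structure(list(pairs = pairs, per_site = per_site),
            class = "incompatibility_report")
}

#' @export
print.incompatibility_report <- function(x, ...) {
  if (nrow(x$pairs) == 0) cat("compatible: perfect phylogeny exists\n")
  else {
    cat(nrow(x$pairs), "incompatible site pair(s):\n")
    print(x$pairs)
  }
  invisible(x)
}

is_compatible <- function(report) nrow(report$pairs) == 0L

#' Resolve four-gamete conflicts at hypermutable sites by site duplication
#'
#' Assumes that each conflict is caused by an independent recurrent
#' mutation at a CpG-hypermutable site.  Each conflicted column is split
#' into two columns (the original and a starred copy, e.g. `25*`) by
#' assigning a subset of its carrier haplotypes to the recurrent copy, such
#' that the expanded matrix passes [four_gamete_check()] with the minimal
#' number of duplications.  Among equivalent splits the smallest carrier
#' subset receives the star.
#'
#' @param bm a `binary_matrix`.
#' @param hypermutable logical vector over columns (default: `bm$cpg`).
#' @return A new `binary_matrix` with starred columns inserted after their
#'   originals; attribute `"recurrence_map"` records, per starred column,
#'   the haplotype ids moved to it.  A matrix that is already compatible is
#'   returned unchanged.
#' @export
resolve_recurrences <- function(bm, hypermutable = bm$cpg) {
  rep0 <- four_gamete_check(bm)
  if (is_compatible(rep0)) return(bm)
  conf <- unique(c(rep0$pairs$site1, rep0$pairs$site2))
  # a conflicted pair has (at least) one recurrent member; only columns that
  # are themselves hypermutable are candidates for duplication
  cand <- conf[hypermutable[match(conf, bm$labels)]]
  if (length(cand) == 0L)
    stop("homoplasy not attributable to CpG recurrence (conflicts: ",
         paste(conf, collapse = ", "), ")")
  non_cand <- setdiff(conf, cand)
  # every conflict must involve at least one candidate
  bad <- rep0$pairs[!(rep0$pairs$site1 %in% cand |
                        rep0$pairs$site2 %in% cand), ]
  if (nrow(bad))
    stop("homoplasy not attributable to CpG recurrence (conflict ",
         bad$site1[1], " / ", bad$site2[1], ")")

  # backtracking search over candidate columns: each conflicted candidate
  # may be split into (original, starred) by any bipartition of its
  # carriers; accept the first assignment (splits ordered by fewest
  # residual conflicts, then smallest starred chromosome count; skipping a
  # candidate is preferred where its conflicts could be fixed by a later
  # candidate) that yields a perfect phylogeny, i.e. the minimal number of
  # duplications under the preference order
  cand <- cand[order(-as.integer(rep0$per_site[cand]))]
  solve <- function(cur, cands_left) {
    chk <- four_gamete_check(cur)
    if (is_compatible(chk)) return(list(bm = cur, map = list()))
    if (!length(cands_left)) return(NULL)
    lab <- cands_left[1]
    rest <- cands_left[-1]
    conf_labs <- unique(c(chk$pairs$site1, chk$pairs$site2))
    if (!lab %in% conf_labs) return(solve(cur, rest))
    mine <- chk$pairs[chk$pairs$site1 == lab | chk$pairs$site2 == lab, ]
    partners <- setdiff(unique(c(mine$site1, mine$site2)), lab)
    options <- list()
    if (all(partners %in% rest)) options <- list(NULL)  # try skipping first
    j <- match(lab, cur$labels)
    carriers <- which(!is.na(cur$x[, j]) & cur$x[, j] == 1L)
    h <- length(carriers)
    if (h >= 2L && h <= 16L) {
      masks <- seq_len(2L^(h - 1L) - 1L)
      scored <- lapply(masks, function(mask) {
        star <- carriers[bitwAnd(bitwShiftL(1L, seq_len(h) - 1L), mask) > 0]
        trial <- split_column(cur, j, star)
        list(star = star, trial = trial,
             nconf = nrow(four_gamete_check(trial)$pairs),
             size = sum(cur$counts[star]))
      })
      ord <- order(vapply(scored, `[[`, 0, "nconf"),
                   vapply(scored, `[[`, 0, "size"))
      options <- c(options, scored[ord])
    } else if (h > 16L) {
      stop("site ", lab, " has too many carriers for exhaustive splitting")
    }
    for (opt in options) {
      if (is.null(opt)) {
        sol <- solve(cur, rest)
      } else {
        sol <- solve(opt$trial, rest)
        if (!is.null(sol))
          sol$map <- c(setNames(list(cur$haplotype_id[opt$star]),
                                paste0(lab, "*")), sol$map)
      }
      if (!is.null(sol)) return(sol)
    }
    NULL
  }
  sol <- solve(bm, cand)
  if (is.null(sol)) {
    final <- four_gamete_check(bm)
    stop("homoplasy not attributable to CpG recurrence; unresolvable conflicts: ",
         paste(unique(c(final$pairs$site1, final$pairs$site2)),
               collapse = ", "))
  }
  out <- sol$bm
  attr(out, "recurrence_map") <- sol$map
  out
}

# split column j of a binary_matrix: carriers in star_rows move to a new
# starred column inserted after j
split_column <- function(bm, j, star_rows) {
  x <- bm$x
  newc <- integer(nrow(x))
  newc[is.na(x[, j])] <- NA_integer_
  newc[star_rows] <- 1L
  x[star_rows, j] <- 0L
  ins <- function(v, at, val) append(v, val, after = at)
  x2 <- cbind(x[, seq_len(j), drop = FALSE], newc,
              if (j < ncol(x)) x[, (j + 1):ncol(x), drop = FALSE])
  lab2 <- ins(bm$labels, j, paste0(bm$labels[j], "*"))
  colnames(x2) <- lab2
  bm$x <- x2
  bm$labels <- lab2
  bm$positions <- ins(bm$positions, j, bm$positions[j])
  bm$cpg <- ins(bm$cpg, j, bm$cpg[j])
  dc <- derived_counts(x2, bm$counts)
  bm$segregating <- dc > 0 & dc < bm$n
  bm
}

#' Build the rooted perfect-phylogeny gene tree
#'
#' Gusfield-style construction for a compatible polarized binary matrix:
#' the root is the all-ancestral haplotype; every mutation labels exactly
#' one edge; every haplotype maps to the node reached by its mutation set.
#' Mutations that share an edge chain (identical carrier sets) are ordered
#' by ascending reference position and flagged order-arbitrary: any of them
#' could be the oldest or youngest.
#'
#' @param bm a compatible `binary_matrix` (run [resolve_recurrences()]
#'   first if [four_gamete_check()] reports conflicts).  Columns
#'   monomorphic within the sample are ignored; mutations carried by every
#'   chromosome are placed on the stem above the sample's MRCA.
#' @return An object of class `gene_tree`: `parent` (node parents; node 1
#'   is the root with parent 0), `mutation` (label on each node's parent
#'   edge), `position`, `tip_mult`, `tip_hap`, `n_sub` (chromosomes
#'   subtended by each node), `n`, and `order_arbitrary` (flag per node:
#'   shares its edge chain with other mutations).
#' @export
build_gene_tree <- function(bm) {
  chk <- four_gamete_check(bm)
  if (!is_compatible(chk))
    stop("matrix is not a perfect phylogeny; resolve_recurrences() first (",
         nrow(chk$pairs), " conflicting pairs)")
  dc <- derived_counts(bm$x, bm$counts)
  use <- which(dc > 0L)
  if (any(is.na(bm$x[, use])))
    stop("missing entries among segregating sites; tree construction needs complete data")
  # global column order: decreasing carrier count, then ascending position
  use <- use[order(-dc[use], bm$positions[use])]
  V <- 1L
  parent <- c(0L)
  mut <- NA_character_
  pos <- NA_integer_
  tip_mult <- 0L
  tip_hap <- NA_character_
  key <- list(integer(0))          # mutation-column sets per node
  node_of <- integer(nrow(bm$x))
  children <- list(integer(0))
  for (r in seq_len(nrow(bm$x))) {
    muts <- use[bm$x[r, use] == 1L]
    cur <- 1L
    for (j in muts) {
      nxt <- 0L
      for (ch in children[[cur]])
        if (mut[ch] == bm$labels[j]) { nxt <- ch; break }
      if (nxt == 0L) {
        V <- V + 1L
        parent[V] <- cur
        mut[V] <- bm$labels[j]
        pos[V] <- bm$positions[j]
        tip_mult[V] <- 0L
        tip_hap[V] <- NA_character_
        children[[cur]] <- c(children[[cur]], V)
        children[[V]] <- integer(0)
        nxt <- V
      }
      cur <- nxt
    }
    if (tip_mult[cur] > 0L)
      stop("two distinct haplotypes map to one node; input rows not unique?")
    tip_mult[cur] <- bm$counts[r]
    tip_hap[cur] <- bm$haplotype_id[r]
    node_of[r] <- cur
  }
  if (V != length(use) + 1L)
    stop("internal error: mutation count mismatch in tree construction")
  # verify reconstruction: each haplotype's root path = its mutation set
  for (r in seq_len(nrow(bm$x))) {
    path <- character(0)
    v <- node_of[r]
    while (v != 1L) { path <- c(path, mut[v]); v <- parent[v] }
    if (!setequal(path, bm$labels[use][bm$x[r, use] == 1L]))
      stop("internal error: leaf state reconstruction failed for ",
           bm$haplotype_id[r])
  }
  n_sub <- tip_mult
  for (v in rev(seq_len(V)[-1])) n_sub[parent[v]] <- n_sub[parent[v]] + n_sub[v]
  # order-arbitrary: node shares an edge chain (parent or single child is a
  # chain link: degree-2 tipless junction)
  nchild <- tabulate(parent[-1], V)
  chain_up <- function(v) parent[v] != 1L &&
    nchild[parent[v]] == 1L && tip_mult[parent[v]] == 0L
  chain_dn <- function(v) nchild[v] == 1L && tip_mult[v] == 0L
  oa <- vapply(seq_len(V), function(v)
    v != 1L && (chain_up(v) || chain_dn(v)), logical(1))
  structure(list(parent = parent, mutation = mut, position = pos,
                 tip_mult = tip_mult, tip_hap = tip_hap, n_sub = n_sub,
                 n = sum(tip_mult), order_arbitrary = oa),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d mutations, %d tips (n = %d chromosomes)\n",
              length(x$parent) - 1L, sum(x$tip_mult > 0), x$n))
  b <- tree_branches(x)
  cat("branches:\n")
  print(head(b, 20))
  if (nrow(b) > 20) cat("...\n")
  invisible(x)
}

#' Branch summary of a gene tree
#'
#' Collapses maximal chains of mutations with identical carrier sets into
#' branches, reporting the ordered mutation labels (`order-arbitrary`
#' within a branch), the subtended chromosome count `n_b` and mutation
#' count `m_b`.
#'
#' @param gt a `gene_tree`.
#' @return data.frame with one row per branch.
#' @export
tree_branches <- function(gt) {
  V <- length(gt$parent)
  nchild <- tabulate(gt$parent[-1], V)
  # branch heads: nodes whose parent is a junction (root, tip-bearing, or >1 child)
  is_junction <- function(v) v == 1L || nchild[v] != 1L || gt$tip_mult[v] > 0L
  heads <- which(seq_len(V) != 1L & vapply(gt$parent, is_junction, TRUE)[seq_len(V)])
  rows <- lapply(heads, function(h) {
    chain <- h
    v <- h
    while (!is_junction(v)) {
      v <- which(gt$parent == v)
      chain <- c(chain, v)
    }
    tipend <- chain[length(chain)]
    data.frame(mutations = paste(gt$mutation[chain], collapse = ","),
               m_b = length(chain), n_b = gt$n_sub[tipend],
               haplotype = gt$tip_hap[tipend],
               end_node = tipend)
  })
  do.call(rbind, rows)
}

# node whose parent edge carries the given mutation label
mutation_node <- function(gt, label) {
  v <- match(label, gt$mutation)
  if (is.na(v)) stop("mutation '", label, "' not in tree")
  v
}

#' Convert a gene tree to an ape "phylo" object
#'
#' Edge lengths are mutation counts; sampled internal haplotypes are
#' attached as zero-length pendant tips.  Tip labels are
#' `<haplotype>:<multiplicity>`.
#'
#' @param x a `gene_tree`.
#' @param ... unused.
#' @return An [ape::as.phylo()] tree.
#' @importFrom ape as.phylo
#' @method as.phylo gene_tree
#' @export
as.phylo.gene_tree <- function(x, ...) {
  V <- length(x$parent)
  nchild <- tabulate(x$parent[-1], V)
  # collapse chains: junction nodes only
  jn <- which(vapply(seq_len(V), function(v)
    v == 1L || nchild[v] != 1L || x$tip_mult[v] > 0L, TRUE))
  up <- function(v) { # nearest junction ancestor + #mutations walked
    d <- 0L
    repeat {
      v <- x$parent[v]; d <- d + 1L
      if (v %in% jn) return(c(v, d))
    }
  }
  lab <- ifelse(is.na(x$tip_hap[jn]), paste0("node", jn),
                sprintf("%s_%d", x$tip_hap[jn], x$tip_mult[jn]))
  is_leaf <- nchild[jn] == 0L
  needs_pendant <- !is_leaf & x$tip_mult[jn] > 0L
  ntip <- sum(is_leaf) + sum(needs_pendant)
  nint <- sum(!is_leaf)
  # phylo ids: tips 1..ntip, internals ntip+1..
  tipid <- integer(length(jn)); intid <- integer(length(jn))
  tipid[is_leaf] <- seq_len(sum(is_leaf))
  intid[!is_leaf] <- ntip + seq_len(nint)
  tip_label <- character(ntip)
  tip_label[tipid[is_leaf]] <- lab[is_leaf]
  edges <- NULL; elen <- NULL
  for (k in seq_along(jn)) {
    v <- jn[k]
    if (v == 1L) next
    ud <- up(v)
    from <- intid[match(ud[1], jn)]
    to <- if (is_leaf[k]) tipid[k] else intid[k]
    edges <- rbind(edges, c(from, to)); elen <- c(elen, ud[2])
  }
  extra <- which(needs_pendant)
  nxt <- sum(is_leaf)
  for (k in extra) {
    nxt <- nxt + 1L
    tip_label[nxt] <- lab[k]
    edges <- rbind(edges, c(intid[k], nxt)); elen <- c(elen, 0)
  }
  phy <- list(edge = edges, edge.length = as.numeric(elen),
              tip.label = tip_label, Nnode = nint,
              node.label = ifelse(is.na(x$tip_hap[jn[!is_leaf]]), "",
                                  lab[!is_leaf]))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a gene tree as Newick
#'
#' @param gt a `gene_tree`.
#' @param path output path.
#' @export
write_newick <- function(gt, path) {
  ape::write.tree(as.phylo(gt), file = path)
  invisible(path)
}

#' Export a gene tree as a haplotype-network edge list
#'
#' TSV with one row per tree edge (branch), carrying the mutation labels,
#' and a node table appended as comment-free second block is avoided:
#' instead per-node haplotype, multiplicity, and (optionally) per-population
#' counts are merged onto the child node of each edge.
#'
#' @param gt a `gene_tree`.
#' @param path output path.
#' @param dataset optional [haplotype_dataset()]; when given, per-population
#'   counts of each node's haplotype are appended.
#' @export
export_network <- function(gt, path, dataset = NULL) {
  b <- tree_branches(gt)
  V <- length(gt$parent)
  nchild <- tabulate(gt$parent[-1], V)
  jn_of <- function(v) { # nearest junction at/above v
    repeat {
      if (v == 1L || nchild[v] != 1L || gt$tip_mult[v] > 0L) return(v)
      v <- gt$parent[v]
    }
  }
  from <- vapply(b$end_node, function(v) jn_of(gt$parent[v]), 0L)
  out <- data.frame(from_node = from, to_node = b$end_node,
                    mutations = b$mutations, m = b$m_b, n_sub = b$n_b,
                    haplotype = b$haplotype,
                    multiplicity = gt$tip_mult[b$end_node])
  if (!is.null(dataset)) {
    idx <- match(out$haplotype, rownames(dataset$counts))
    cnts <- dataset$counts[idx, , drop = FALSE]
    cnts[is.na(idx), ] <- NA
    colnames(cnts) <- paste0("count_", dataset$populations$name)
    out <- cbind(out, cnts)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
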