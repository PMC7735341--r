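#' Agglomerative clustering of a similarity matrix
#'
#' Clusters items hierarchically on the dissimilarity `1 - similarity`.
#' Supported linkages are the three used for song comparison: unweighted
#' average linkage (UPGMA, the default), single linkage, and weighted
#' average linkage (WPGMA / McQuitty). The choice between them is made by
#' comparing cophenetic correlation coefficients
#' ([cophenetic_correlation()]); a CCC above 0.8 is conventionally
#' considered a good representation of the data.
#'
#' @param sim A similarity matrix (validated with
#'   [validate_similarity_matrix()]).
#' @param method `"average"`, `"single"` or `"weighted_average"`.
#' @return An [stats::hclust] tree; heights are average (or single)
#'   linkage dissimilarities in \[0, 1\].
#' @export
linkage_cluster <- function(sim,
                            method = c("average", "single",
                                       "weighted_average")) {
  method <- match.arg(method)
  validate_similarity_matrix(sim)
  hmethod <- c(average = "average", single = "single",
               weighted_average = "mcquitty")[[method]]
  hclust(as.dist(1 - sim), method = hmethod)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the cophenetic distances implied by a
#' dendrogram and the original dissimilarities (`1 - similarity`) over all
#' item pairs. Used to pick the linkage method that best preserves the
#' similarity structure; values above 0.8 are conventionally "good".
#'
#' @param dend An [stats::hclust] tree over the same items as `sim`.
#' @param sim The similarity matrix the tree was built from.
#' @return A correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(dend, sim) {
  validate_similarity_matrix(sim)
  labs <- dend$labels
  if (!is.null(labs) && !is.null(rownames(sim))) {
    if (!setequal(labs, rownames(sim))) {
      stop("dendrogram and similarity matrix label mismatch",
           call. = FALSE)
    }
    sim <- sim[labs, labs]
  } else if (length(dend$order) != nrow(sim)) {
    stop("dendrogram and similarity matrix size mismatch", call. = FALSE)
  }
  cor(as.vector(cophenetic(dend)), as.vector(as.dist(1 - sim)))
}

#' Convenience: phrase-string clustering CCCs
#'
#' Builds the LSI similarity matrix over all phrase strings of a phrase
#' table and reports the cophenetic correlation coefficient of each
#' requested linkage, for linkage selection.
#'
#' @param phrases A validated phrase table.
#' @param methods Linkage methods to compare.
#' @return Named numeric vector of CCC values.
#' @export
phrase_clustering_ccc <- function(phrases,
                                  methods = c("average", "single",
                                              "weighted_average")) {
  phrases <- validate_phrase_table(phrases)
  m <- similarity_matrix(split_units(phrases$units),
                         labels = paste0("p", seq_len(nrow(phrases))))
  vapply(methods,
         function(meth) cophenetic_correlation(
           linkage_cluster(m, meth), m),
         numeric(1))
}

# Leaf index sets of every internal node of an hclust tree, in merge order.
merge_leaf_sets <- function(merge) {
  n <- nrow(merge) + 1L
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    leaves <- integer(0)
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) -k else sets[[k]])
    }
    sets[[i]] <- sort.int(leaves)
  }
  sets
}

edge_keys <- function(hc) {
  vapply(merge_leaf_sets(hc$merge), paste, character(1), collapse = ",")
}

#' Leaf-label sets of dendrogram edges
#'
#' Every internal node of the tree defines an edge whose support can be
#' assessed: the set of leaves below it. Returned in merge order (last =
#' root, containing all leaves).
#'
#' @param dend An [stats::hclust] tree.
#' @return A list of character vectors of leaf labels.
#' @export
edge_leaf_sets <- function(dend) {
  labs <- dend$labels
  if (is.null(labs)) labs <- as.character(seq_len(length(dend$order)))
  lapply(merge_leaf_sets(dend$merge), function(i) labs[i])
}

#' Default multiscale-bootstrap resampling ratios
#'
#' Ten ratios log-spaced over \[1/range, range\], with the grid point
#' nearest 1 snapped to exactly 1.0 so that the plain bootstrap scale is
#' always among them.
#'
#' @param n Number of ratios.
#' @param range Upper ratio bound (lower bound is its reciprocal).
#' @return Sorted numeric vector of resampling ratios including 1.0.
#' @export
bootstrap_scales <- function(n = 10, range = 1.4) {
  r <- exp(seq(-log(range), log(range), length.out = n))
  r[which.min(abs(r - 1))] <- 1
  r
}

# Weighted least-squares fit of the multiscale bootstrap profile for one
# edge. z = qnorm(1 - BP) is modelled as v*sqrt(sigma2) + c/sqrt(sigma2)
# with sigma2 = 1/r; the approximately-unbiased support is then
# AU = 1 - pnorm(v - c), and the bias-corrected BP is 1 - pnorm(v + c).
au_fit <- function(bp, scales, B) {
  stopifnot(length(bp) == length(scales))
  if (all(bp >= 1)) {
    return(list(au = 1, bp_corr = 1, v = NA_real_, c = NA_real_,
                degenerate = FALSE))
  }
  if (all(bp <= 0)) {
    return(list(au = 0, bp_corr = 0, v = NA_real_, c = NA_real_,
                degenerate = FALSE))
  }
  use <- bp > 0 & bp < 1
  if (sum(use) < 2L) {
    bp1 <- bp[which.min(abs(scales - 1))]
    return(list(au = bp1, bp_corr = bp1, v = NA_real_, c = NA_real_,
                degenerate = TRUE))
  }
  sig2 <- 1 / scales[use]
  z <- qnorm(1 - bp[use])
  w <- B * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  X <- cbind(sqrt(sig2), 1 / sqrt(sig2))
  fit <- lm.wfit(X, z, w)
  v <- fit$coefficients[[1L]]
  cc <- fit$coefficients[[2L]]
  if (!is.finite(v) || !is.finite(cc)) {
    bp1 <- bp[which.min(abs(scales - 1))]
    return(list(au = bp1, bp_corr = bp1, v = NA_real_, c = NA_real_,
                degenerate = TRUE))
  }
  list(au = 1 - pnorm(v - cc), bp_corr = 1 - pnorm(v + cc),
       v = v, c = cc, degenerate = FALSE)
}

#' Multiscale bootstrap support for song clustering
#'
#' Assesses the stability of a dendrogram built from grouped string data.
#' Each group (typically one recording) holds the member strings (song
#' cycles or phrase renditions) behind one dendrogram leaf. For every
#' resampling ratio `r`, each group's members are resampled with
#' replacement to size `round(r * n)`, the group-level similarity matrix
#' and dendrogram are recomputed, and the bootstrap proportion BP(edge, r)
#' is the fraction of replicates containing the edge's exact leaf set.
#' The approximately-unbiased (AU) support of each edge is obtained from
#' the multiscale BP profile by a weighted least-squares fit of
#' `qnorm(1 - BP)` against `sqrt(1/r)` and `sqrt(r)` (see [au_fit]
#' internals); AU above 0.95 is conventionally taken as a stable division.
#'
#' Two cluster targets are available, mirroring the two song-level LSI
#' analyses: `"median"` represents each group by its median string (point
#' estimate); `"full"` uses the mean cross-group pairwise LSI over all
#' member strings, retaining within-group variability.
#'
#' Edges present in every replicate at every scale get AU = 1; edges whose
#' profile cannot support the two-parameter fit fall back to BP at r = 1
#' and are flagged `degenerate`. With `scales = 1` the method degrades to
#' the ordinary bootstrap and AU equals BP.
#'
#' @param groups Named list; each element is the collection of member
#'   strings of one leaf (a list of symbol vectors, or a character vector
#'   of space-delimited strings).
#' @param cluster_target `"median"` or `"full"` (see above).
#' @param B Bootstrap replicates per scale.
#' @param scales Resampling ratios; must include 1.0. Scales under which
#'   any group would shrink below one member are skipped with a warning.
#' @param seed Integer master seed; per-scale streams are spawned from it
#'   so results are identical for identical seeds regardless of scale
#'   order.
#' @param method Linkage method (see [linkage_cluster()]).
#' @return An object of class `"edge_support"`: a data frame with one row
#'   per internal edge of the observed dendrogram — `edge` (index in merge
#'   order), `leaves` (comma-joined leaf labels), `bp` (bootstrap
#'   proportion at r = 1), `au`, `v`, `c` (fitted signed distance and
#'   curvature) and `degenerate`. The observed tree, the per-scale BP
#'   profile matrix, and the scales used are attached as attributes
#'   `"dendrogram"`, `"bp_profile"` and `"scales"`.
#' @export
bootstrap_support <- function(groups,
                              cluster_target = c("median", "full"),
                              B = 1000, scales = bootstrap_scales(),
                              seed = NULL, method = "average") {
  cluster_target <- match.arg(cluster_target)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!any(abs(scales - 1) < 1e-12)) {
    stop("scales must include 1.0", call. = FALSE)
  }
  if (length(groups) < 3L) {
    stop("bootstrap_support() needs at least 3 groups", call. = FALSE)
  }
  seqs <- lapply(groups, as_symbol_sequences)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  n_mem <- vapply(seqs, length, integer(1))
  # shared alphabet across all members of all groups
  flat <- unlist(seqs, recursive = FALSE, use.names = FALSE)
  enc_flat <- encode_sequences(flat)
  enc <- split(enc_flat, rep(seq_along(seqs), n_mem))
  target_code <- if (cluster_target == "median") 0L else 1L

  full_idx <- lapply(n_mem, seq_len)
  obs_sim <- group_sim_matrix_cpp(enc, full_idx, target_code)
  dimnames(obs_sim) <- list(labs, labs)
  obs_hc <- linkage_cluster(obs_sim, method)
  obs_keys <- edge_keys(obs_hc)
  n_edge <- length(obs_keys)

  if (!is.null(seed)) set.seed(seed)
  scale_seeds <- sample.int(.Machine$integer.max - 1L, length(scales))
  bp <- matrix(NA_real_, n_edge, length(scales),
               dimnames = list(NULL, format(scales, digits = 4)))
  used <- logical(length(scales))
  for (k in seq_along(scales)) {
    sizes <- pmax(0L, as.integer(round(scales[k] * n_mem)))
    if (any(sizes < 1L)) {
      warning("scale ", format(scales[k], digits = 3),
              " skipped: a group would have no members", call. = FALSE)
      next
    }
    used[k] <- TRUE
    set.seed(scale_seeds[k])
    hits <- numeric(n_edge)
    for (b in seq_len(B)) {
      idx <- lapply(seq_along(enc),
                    function(g) sample.int(n_mem[g], sizes[g],
                                           replace = TRUE))
      m <- group_sim_matrix_cpp(enc, idx, target_code)
      hc <- hclust(as.dist(1 - m), method = obs_hc$method)
      hits <- hits + (obs_keys %in% edge_keys(hc))
    }
    bp[, k] <- hits / B
  }
  if (!any(used)) stop("all scales were skipped", call. = FALSE)

  fits <- lapply(seq_len(n_edge),
                 function(e) au_fit(bp[e, used], scales[used], B))
  r1 <- which(abs(scales - 1) < 1e-12)[1L]
  leaf_sets <- edge_leaf_sets(obs_hc)
  out <- data.frame(
    edge = seq_len(n_edge),
    leaves = vapply(leaf_sets, paste, character(1), collapse = ","),
    bp = bp[, r1],
    au = vapply(fits, `[[`, numeric(1), "au"),
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("edge_support", "data.frame")
  attr(out, "dendrogram") <- obs_hc
  attr(out, "bp_profile") <- bp[, used, drop = FALSE]
  attr(out, "scales") <- scales[used]
  out
}

#' Support for a known partition
#'
#' Looks up the AU (and BP) support of the edge whose leaf set equals a
#' given group of labels or its complement — e.g. the split between two
#' song lineages known from ground truth. Returns support 0 if no such
#' edge exists in the observed tree.
#'
#' @param support An `"edge_support"` result from [bootstrap_support()].
#' @param members Character vector of leaf labels on one side of the
#'   partition.
#' @return A list with `au`, `bp` and `found`.
#' @export
partition_support <- function(support, members) {
  hc <- attr(support, "dendrogram")
  labs <- hc$labels
  key1 <- paste(sort(match(members, labs)), collapse = ",")
  key2 <- paste(sort(match(setdiff(labs, members), labs)), collapse = ",")
  keys <- edge_keys(hc)
  hit <- which(keys %in% c(key1, key2))
  # the root (all leaves) is trivially present; prefer a proper edge
  hit <- hit[hit < length(keys)]
  if (!length(hit)) return(list(au = 0, bp = 0, found = FALSE))
  e <- hit[1L]
  list(au = support$au[e], bp = support$bp[e], found = TRUE)
}

#' Export a supported dendrogram as Newick
#'
#' Writes the tree in Newick format with support values as internal-node
#' labels, readable by standard phylogenetics software.
#'
#' @param dend An [stats::hclust] tree.
#' @param support Optional `"edge_support"` table from
#'   [bootstrap_support()] over the same leaves; its AU values (or BP when
#'   `value = "bp"`) label the matching internal nodes.
#' @param path Output file path.
#' @param value `"au"` or `"bp"`.
#' @return The [ape::phylo] tree, invisibly.
#' @export
write_newick <- function(dend, path, support = NULL, value = c("au", "bp")) {
  value <- match.arg(value)
  phy <- ape::as.phylo(dend)
  if (!is.null(support)) {
    labs <- dend$labels
    hc_keys <- vapply(edge_leaf_sets(dend),
                      function(x) paste(sort(x), collapse = ","),
                      character(1))
    vals <- support[[value]][match(hc_keys, vapply(
      strsplit(support$leaves, ","),
      function(x) paste(sort(x), collapse = ","), character(1)))]
    # phylo internal nodes: map each to its clade's leaf set
    n_tip <- length(phy$tip.label)
    node_lab <- character(phy$Nnode)
    clades <- ape::prop.part(phy)
    for (i in seq_along(clades)) {
      key <- paste(sort(phy$tip.label[clades[[i]]]), collapse = ",")
      j <- match(key, hc_keys)
      node_lab[i] <- if (!is.na(j) && is.finite(vals[j])) {
        format(round(vals[j], 3))
      } else ""
    }
    phy$node.label <- node_lab
  }
  ape::write.tree(phy, file = path)
  invisible(phy)
}
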