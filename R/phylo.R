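TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Pairwise evolutionary distance between two aligned rows
#'
#' Sites with a gap or `N` in either row are excluded (pairwise deletion).
#' The p-distance is the mismatch fraction; the Kimura 2-parameter distance
#' is `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition
#' and `Q` the transversion fraction.
#'
#' @param row_i,row_j equal-length gapped DNA strings.
#' @param model `"p"` or `"k2p"`.
#' @return list (`distance_result`): `d`, `P`, `Q`, `sites_compared`.
#' @export
pairwise_distance <- function(row_i, row_j, model = c("p", "k2p")) {
  model <- match.arg(model)
  a <- seq_chars(toupper(row_i)); b <- seq_chars(toupper(row_j))
  if (length(a) != length(b)) stop("rows must have equal length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("undefined distance: zero comparable sites")
  diff <- a != b
  ts <- diff & (TRANSITIONS[a] == b)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  d <- if (model == "p") {
    P + Q
  } else {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) {
      stop("K2P saturation: log argument <= 0 (P=", signif(P, 4),
           ", Q=", signif(Q, 4), ")")
    }
    -0.5 * log(w1) - 0.25 * log(w2)
  }
  structure(list(d = d, P = P, Q = Q, sites_compared = n),
            class = "distance_result")
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln alignment ([as_alignment()] / [read_alignment()]).
#' @param model `"p"` or `"k2p"`.
#' @return symmetric numeric matrix with row/column names from the
#'   alignment. Pairs with zero comparable sites or K2P saturation get `NA`.
#' @export
distance_matrix <- function(aln, model = c("p", "k2p")) {
  model <- match.arg(model)
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  ok <- matrix(mat %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nn <- sum(both)
      if (nn == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
      a <- mat[i, both]; b <- mat[j, both]
      diff <- a != b
      ts <- diff & (TRANSITIONS[a] == b)
      P <- sum(ts) / nn; Q <- sum(diff & !ts) / nn
      val <- if (model == "p") P + Q else {
        w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0) NA_real_ else
          -0.5 * log(w1) - 0.25 * log(w2)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); on an additive matrix the
#' true topology and branch lengths are recovered exactly. Negative branch
#' lengths are clamped to zero (with a warning).
#'
#' @param d symmetric numeric distance matrix (n >= 3, finite entries).
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Nonparametric bootstrap of the NJ tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate alignment yields an NJ tree, and the support of each internal
#' branch of the original tree is the percentage of replicate trees
#' containing the same bipartition. Replicates with undefined distances are
#' skipped and counted.
#'
#' @param aln alignment.
#' @param n_reps number of replicates (>= 1; default 1000).
#' @param model distance model.
#' @param seed integer seed (resampling is deterministic given the seed).
#' @return the NJ tree of the full alignment, midpoint-rooted so that
#'   well-separated groups appear as clades, with `node.label` set to
#'   integer percent supports, plus attributes `n_reps_used` and
#'   `n_skipped`.
#' @export
bootstrap_nj <- function(aln, n_reps = 1000L, model = "k2p", seed = 1L) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  d0 <- distance_matrix(aln, model)
  if (any(!is.finite(d0))) stop("undefined distances in the full alignment")
  if (all(d0 == 0)) {
    # identical sequences: the tree has no internal structure and supports
    # are undefined; report an unresolved topology with zero supports
    ref <- suppressWarnings(nj_tree(d0))
    ref$node.label <- rep("0", ref$Nnode)
    attr(ref, "n_reps_used") <- 0L
    attr(ref, "n_skipped") <- 0L
    attr(ref, "degenerate") <- TRUE
    return(ref)
  }
  ref <- phangorn::midpoint(nj_tree(d0))
  ncol <- nchar(aln[[1]])
  mat <- alignment_matrix(aln)
  trees <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol, ncol, replace = TRUE)
    rep_aln <- as_alignment(setNames(
      apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
      names(aln)))
    dr <- distance_matrix(rep_aln, model)
    if (any(!is.finite(dr))) { skipped <- skipped + 1L; next }
    trees[[r]] <- suppressWarnings(nj_tree(dr))
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  used <- length(trees)
  if (used == 0L) stop("all bootstrap replicates had undefined distances")
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / used))
  attr(ref, "n_reps_used") <- used
  attr(ref, "n_skipped") <- skipped
  ref
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent base among A/C/G/T wins; base ties are
#' broken alphabetically. Columns where the gap character is the plurality
#' are dropped.
#'
#' @param aln alignment with at least 2 rows.
#' @return ungapped consensus DNA string.
#' @export
majority_consensus <- function(aln) {
  if (length(aln) < 2L) stop("need at least 2 rows")
  mat <- alignment_matrix(aln)
  apply_col <- function(col) {
    n_gap <- sum(!col %in% DNA_BASES)
    tab <- table(factor(col[col %in% DNA_BASES], levels = DNA_BASES))
    if (all(tab == 0L) || n_gap > max(tab)) return("")
    DNA_BASES[which.max(tab)] # which.max takes the first = alphabetical tie
  }
  paste(apply(mat, 2, apply_col), collapse = "")
}

#' Extract bootstrap-supported subgroups from a tree
#'
#' Maximal clades with bootstrap support at least `support_threshold`
#' percent and at least `min_size` tips become subgroups, labeled `A`, `B`,
#' ... in decreasing size order. Supported clades nested inside a subgroup
#' become sub-labels (`B1`, `B2`, ...). Remaining tips are labeled
#' `"other"`.
#'
#' @param tree an [ape::phylo] with integer percent supports in
#'   `node.label` (e.g. from [bootstrap_nj()]).
#' @param support_threshold minimum support, percent (default 70).
#' @param min_size minimum clade size (default 5).
#' @return list: `assignment` (data.frame `locus_id, label`), `clades`
#'   (data.frame `label, support, size`).
#' @export
extract_subgroups <- function(tree, support_threshold = 70, min_size = 5L) {
  if (is.null(tree$node.label)) stop("tree has no support values")
  ntip <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  # tip sets per internal node
  clade_tips <- function(node) {
    tips <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[[1]]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      tips <- c(tips, kids[kids <= ntip])
      stack <- c(stack, kids[kids > ntip])
    }
    tips
  }
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  sets <- lapply(nodes, clade_tips)
  sizes <- lengths(sets)
  eligible <- which(!is.na(supports) & supports >= support_threshold &
                      sizes >= min_size & sizes < ntip)
  assignment <- data.frame(locus_id = tree$tip.label,
                           label = rep("other", ntip),
                           stringsAsFactors = FALSE)
  clades <- data.frame(label = character(0), support = numeric(0),
                       size = integer(0), stringsAsFactors = FALSE)
  if (length(eligible)) {
    # maximal eligible clades (not contained in another eligible clade)
    contained <- vapply(eligible, function(i) {
      any(vapply(eligible, function(j) {
        i != j && sizes[j] > sizes[i] && all(sets[[i]] %in% sets[[j]])
      }, logical(1)))
    }, logical(1))
    top <- eligible[!contained]
    top <- top[order(-sizes[top])]
    for (k in seq_along(top)) {
      lab <- LETTERS[k]
      i <- top[k]
      assignment$label[sets[[i]]] <- lab
      clades <- rbind(clades, data.frame(label = lab,
                                         support = supports[i],
                                         size = sizes[i]))
      nested <- eligible[contained][vapply(eligible[contained], function(j) {
        all(sets[[j]] %in% sets[[i]])
      }, logical(1))]
      if (length(nested)) {
        # maximal nested clades become sub-labels
        nn_contained <- vapply(nested, function(a) {
          any(vapply(nested, function(b) {
            a != b && sizes[b] > sizes[a] && all(sets[[a]] %in% sets[[b]])
          }, logical(1)))
        }, logical(1))
        subtop <- nested[!nn_contained]
        subtop <- subtop[order(-sizes[subtop])]
        for (m in seq_along(subtop)) {
          sublab <- paste0(lab, m)
          assignment$label[sets[[subtop[m]]]] <- sublab
          clades <- rbind(clades, data.frame(label = sublab,
                                             support = supports[subtop[m]],
                                             size = sizes[subtop[m]]))
        }
      }
    }
  }
  list(assignment = assignment, clades = clades)
}
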