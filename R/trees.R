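#' Build a starting topology from a distance matrix
#'
#' Neighbour-joining (classic Q-criterion, via \pkg{ape}) or BioNJ
#' (Gascuel's variance-weighted reduction, implemented here in double
#' precision). Both are exact on additive matrices. Negative branch lengths
#' produced by either agglomeration are clamped to zero with a warning.
#'
#' @param dm Symmetric numeric matrix with zero diagonal (>= 3 taxa).
#' @param method `"NJ"` or `"BioNJ"`.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_tree <- function(dm, method = c("NJ", "BioNJ")) {
  method <- match.arg(method)
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least three taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal is not zero")
  tree <- switch(method, NJ = ape::nj(dm), BioNJ = bionj_double(dm))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to zero (",
            method, ")")
    tree$edge.length[neg] <- 0
  }
  tree
}

# BioNJ agglomeration (Gascuel 1997) in double precision: alongside the
# distance matrix a variance matrix (initialised to the distances) steers the
# reduction weight lambda; pair selection uses the classic Q criterion.
bionj_double <- function(dm) {
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(dm)))
  D <- dm
  V <- dm
  # newick fragment per active node
  frag <- taxa
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    S <- rowSums(D)
    Qc <- (r - 2) * D - outer(S, S, "+")
    diag(Qc) <- Inf
    ij <- arrayInd(which.min(Qc), dim(Qc))
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    ks <- setdiff(seq_len(r), c(i, j))
    lambda <- if (V[i, j] > 0) {
      0.5 + sum(V[j, ks] - V[i, ks]) / (2 * (r - 2) * V[i, j])
    } else 0.5
    lambda <- min(1, max(0, lambda))
    Du <- lambda * D[i, ks] + (1 - lambda) * D[j, ks] -
      lambda * li - (1 - lambda) * lj
    Vu <- lambda * V[i, ks] + (1 - lambda) * V[j, ks] -
      lambda * (1 - lambda) * V[i, j]
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
                       fmt(lj), ")")
    keep <- ks
    D <- rbind(cbind(D[keep, keep, drop = FALSE], Du),
               c(Du, 0))
    V <- rbind(cbind(V[keep, keep, drop = FALSE], Vu),
               c(Vu, 0))
    frag <- c(frag[keep], new_frag)
  }
  # final three-point resolution
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Nearest-clade population summary for query taxa
#'
#' For each query leaf, the smallest non-trivial clade containing it (the
#' clade of its immediate ancestor) is inspected: the population labels of
#' its co-members are tallied and the majority label is reported as the
#' "clustered-with" call. A balanced composition is called `"mixed"`; a
#' singleton sister leaf contributes its own label directly.
#'
#' @param tree `ape::phylo` tree.
#' @param labels Named character vector mapping every non-query taxon (at
#'   least) to a population label.
#' @param queries Character vector of query tip labels (must be in the tree).
#' @return Data frame with columns `query`, `clade_size` (co-member count),
#'   `composition` (label=count pairs) and `call`.
#' @export
clade_label_report <- function(tree, labels, queries) {
  missing_q <- setdiff(queries, tree$tip.label)
  if (length(missing_q) > 0L) {
    stop("query taxa not in tree: ", paste(missing_q, collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  rows <- lapply(queries, function(q) {
    tip <- match(q, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2L] == tip, 1L]
    members <- clade_tips(tree, parent, n_tip)
    co <- setdiff(tree$tip.label[members], q)
    # co-members that are themselves queries carry no reference label
    co_labels <- labels[co]
    co_labels <- co_labels[!is.na(co_labels)]
    if (length(co_labels) == 0L) {
      return(data.frame(query = q, clade_size = length(co),
                        composition = "", call = "unresolved",
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(co_labels), decreasing = TRUE)
    call <- if (length(tab) > 1L && tab[1L] == tab[2L]) "mixed" else
      names(tab)[1L]
    data.frame(query = q, clade_size = length(co),
               composition = paste(names(tab), tab, sep = "=",
                                   collapse = ";"),
               call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tip indices descending from an internal node
clade_tips <- function(tree, node, n_tip) {
  if (node <= n_tip) return(node)
  out <- integer(0)
  frontier <- node
  while (length(frontier) > 0L) {
    kids <- tree$edge[tree$edge[, 1L] %in% frontier, 2L]
    out <- c(out, kids[kids <= n_tip])
    frontier <- kids[kids > n_tip]
  }
  out
}

#' Write a tree to a newick file
#' @param tree `ape::phylo` tree.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Newick file path.
#' @return `ape::phylo` tree.
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
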