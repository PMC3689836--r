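# Ancestral-state reconstruction on the (possibly multifurcating) composite
# cladogram: unordered parsimony for discrete characters, Brownian-motion
# generalized least squares for continuous traits.

.state_sets <- function(states, tips, levels = NULL) {
  if (is.null(names(states))) names(states) <- tips
  states <- states[tips]
  split_states <- strsplit(ifelse(is.na(states), "", states), "/", fixed = TRUE)
  if (is.null(levels)) levels <- sort(unique(unlist(split_states)))
  levels <- levels[nzchar(levels)]
  if (length(levels) < 1) stop("all tips missing; nothing to reconstruct")
  list(levels = levels, sets = split_states)
}

#' Parsimony ancestral states for an unordered discrete character
#'
#' Uniform-cost Sankoff dynamic programming, which generalizes Fitch
#' parsimony to multistate characters and multifurcating trees.  An up-pass
#' computes, for every node and state, the minimal number of changes in the
#' subtree; a down-pass adds the cost of the rest of the tree, so each
#' node's reported set contains exactly the states attained in at least one
#' globally most-parsimonious reconstruction ("equivocal" nodes have more
#' than one).  Missing tips (and polymorphic tips, coded
#' \code{"stateA/stateB"}) contribute no cost for any of their allowed
#' states.
#'
#' @param tree \code{phylo} object, rooted; polytomies allowed.
#' @param states named character vector of tip states (names = tip labels),
#'   \code{NA} for missing.
#' @param levels optional explicit state universe.
#' @return List of class \code{parsimony_asr}: \code{length} (tree length in
#'   steps), \code{node_states} (list of optimal state sets per node,
#'   indexed by ape node number), \code{equivocal} (logical per node), and
#'   \code{levels}.
#' @export
parsimony_asr <- function(tree, states, levels = NULL) {
  ss <- .state_sets(states, tree$tip.label, levels)
  k <- length(ss$levels)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  N <- ntip + nnode
  S <- matrix(Inf, N, k)
  for (i in seq_len(ntip)) {
    allowed <- ss$sets[[i]]
    if (length(allowed) == 0) S[i, ] <- 0
    else {
      idx <- match(allowed, ss$levels)
      if (anyNA(idx)) stop("tip state outside declared levels: ",
                           paste(allowed[is.na(idx)], collapse = ", "))
      S[i, idx] <- 0
    }
  }
  tre <- stats::reorder(tree, "postorder")
  edge <- tre$edge
  contrib <- function(Srow) pmin(Srow, min(Srow) + 1)
  for (r in seq_len(nrow(edge))) {
    par <- edge[r, 1]; chi <- edge[r, 2]
    if (all(!is.finite(S[par, ]))) S[par, ] <- 0
    S[par, ] <- S[par, ] + contrib(S[chi, ])
  }
  root <- ntip + 1
  # outside costs: O[v, s] = best cost of the tree minus the subtree at v,
  # given the edge into v ends in state s
  O <- matrix(0, N, k)
  children <- split(edge[, 2], edge[, 1])
  preord <- rev(seq_len(nrow(edge)))
  for (r in preord) {
    par <- edge[r, 1]; chi <- edge[r, 2]
    sibs <- setdiff(children[[as.character(par)]], chi)
    M <- O[par, ]
    for (b in sibs) M <- M + contrib(S[b, ])
    O[chi, ] <- pmin(M, min(M) + 1)
  }
  tot <- S + O
  best <- apply(tot, 1, min)
  node_states <- lapply(seq_len(N), function(v) ss$levels[tot[v, ] <= best[v] + 1e-9])
  structure(list(length = min(S[root, ]),
                 node_states = node_states,
                 equivocal = vapply(node_states, length, 1L) > 1,
                 levels = ss$levels, ntip = ntip),
            class = "parsimony_asr")
}

#' Brownian-motion ancestral states for a continuous trait
#'
#' Generalized-least-squares point estimates under Brownian motion,
#' equivalently the minimizer of the branch-length-weighted sum of squared
#' changes \eqn{\sum_e (\Delta x_e)^2 / \ell_e}.  The normal equations form
#' a weighted graph Laplacian over the tree; with tips fixed at their
#' observed values the internal states are the exact solution of that
#' linear system (no iteration).  Tips with missing values are treated as
#' free nodes, which marginalizes them out.  On a star tree with equal
#' branch lengths the root estimate reduces to the tip mean.
#'
#' @param tree \code{phylo}; polytomies allowed.
#' @param values named numeric vector of tip values (names = tip labels);
#'   \code{NA} allowed.
#' @param branch_lengths optional override; default: the tree's own lengths,
#'   or 1 on every edge if absent.  All lengths must be positive.
#' @return List of class \code{brownian_asr}: \code{estimates} (length
#'   ntip+nnode; tips reproduce their observed values), \code{ntip}.
#' @export
brownian_asr <- function(tree, values, branch_lengths = NULL) {
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  if (is.null(branch_lengths)) branch_lengths <- tree$edge.length
  if (is.null(branch_lengths)) branch_lengths <- rep(1, nrow(tree$edge))
  if (any(branch_lengths <= 0)) stop("branch lengths must be positive")
  if (is.null(names(values))) names(values) <- tree$tip.label
  x <- rep(NA_real_, N)
  x[seq_len(ntip)] <- as.numeric(values[tree$tip.label])
  if (all(is.na(x[seq_len(ntip)]))) stop("all tip values missing")
  free <- which(is.na(x) | seq_len(N) > ntip)
  fixed <- setdiff(seq_len(N), free)
  w <- 1 / branch_lengths
  A <- matrix(0, length(free), length(free))
  b <- numeric(length(free))
  fidx <- match(seq_len(N), free)
  for (r in seq_len(nrow(tree$edge))) {
    i <- tree$edge[r, 1]; j <- tree$edge[r, 2]; we <- w[r]
    fi <- fidx[i]; fj <- fidx[j]
    if (!is.na(fi)) A[fi, fi] <- A[fi, fi] + we
    if (!is.na(fj)) A[fj, fj] <- A[fj, fj] + we
    if (!is.na(fi) && !is.na(fj)) {
      A[fi, fj] <- A[fi, fj] - we
      A[fj, fi] <- A[fj, fi] - we
    } else if (!is.na(fi)) b[fi] <- b[fi] + we * x[j]
    else if (!is.na(fj)) b[fj] <- b[fj] + we * x[i]
  }
  x[free] <- solve(A, b)
  structure(list(estimates = x, ntip = ntip), class = "brownian_asr")
}

#' Ancestral reconstruction table for all labyrinth characters
#'
#' Runs \code{\link{parsimony_asr}} over the six discrete labyrinth
#' characters and \code{\link{brownian_asr}} over cochlear coiling and the
#' cochlear volumetric contribution, and reports one row per labelled
#' internal node of the cladogram.  Equivocal discrete reconstructions are
#' printed as slash-joined state lists.
#'
#' @param tree labelled cladogram from \code{\link{load_tree}}.
#' @param measurements data frame from \code{\link{load_measurements}}.
#' @return Data frame, one row per labelled internal node, with the six
#'   character columns, \code{coil_deg} and \code{cochlear_pct}.
#' @export
reconstruct_all <- function(tree, measurements) {
  cm <- character_matrix(measurements)
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
    stop("tree has no labelled internal nodes")
  keep <- which(nzchar(tree$node.label))
  node_ids <- ntip + keep
  out <- data.frame(node = tree$node.label[keep], stringsAsFactors = FALSE)
  for (ch in c("c1_lsc_entry", "c2_lsc_position", "c3_largest_canal",
               "c4_cochlea_shape", "c5_coil_bin", "c6_cochlea_contribution_bin")) {
    states <- stats::setNames(cm[[ch]], cm$taxon_id)
    rec <- parsimony_asr(tree, states)
    out[[ch]] <- vapply(rec$node_states[node_ids], paste, "", collapse = "/")
  }
  coil <- stats::setNames(measurements$cochlea_coil_deg, measurements$taxon_id)
  contrib <- volumetric_contributions(measurements$cochlea_volume_mm3,
                                      measurements$labyrinth_volume_mm3)$cochlear_pct
  names(contrib) <- measurements$taxon_id
  out$coil_deg <- brownian_asr(tree, coil)$estimates[node_ids]
  out$cochlear_pct <- brownian_asr(tree, contrib)$estimates[node_ids]
  out
}
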