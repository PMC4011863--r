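# Time trees and phylogenetic covariance matrices.
#
# Trees are ape "phylo" objects with branch lengths in Myr. Covariance
# matrices are plain numeric matrices whose dimnames carry the tip order;
# V[i, j] is the shared root-to-tip path length of tips i and j, so for an
# ultrametric tree diag(V) equals the tree depth.

#' Read a time-calibrated tree from a Newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. Every edge must carry
#' a branch length and tip labels must be unique; violations raise an error
#' naming the offending token rather than propagating silently into the
#' covariance algebra downstream.
#'
#' @param text Newick string (e.g. `"((a:1,b:1):1,c:2);"`). Exactly one of
#'   `text`/`file` must be given.
#' @param file Path to a Newick file.
#' @return An object of class `"phylo"` with branch lengths in Myr.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' tree_depth(tr) # 2
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0)
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(tr$tip.label)))
    stop("empty tip label in Newick input")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("missing branch length on at least one edge")
  if (any(tr$edge.length < 0))
    stop("negative branch length: ", min(tr$edge.length))
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths. The default of 12
#'   round-trips Myr-scale branch lengths through text to better than 1e-9.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Root-to-tip depth of a tree
#'
#' @param tree A `"phylo"` object.
#' @return Maximum root-to-tip path length (Myr).
#' @export
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Check ultrametricity
#'
#' A chronogram should have equal root-to-tip path lengths; Newick text
#' written at finite precision drifts slightly, so the check is relative.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on root-to-tip depths (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `V[i, j]` is the branch length shared by tips i and j on their paths from
#' the root; `V[i, i]` is the root-to-tip depth. Under Brownian motion the
#' tip values are jointly normal with covariance `sigma2 * V`.
#'
#' @param tree A `"phylo"` object, expected (but not required) ultrametric.
#' @return Symmetric matrix with `tree$tip.label` as dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) > 1 && !is_ultrametric(tree))
    warning("tree is not ultrametric within relative tolerance 1e-6; ",
            "covariance diagonal will be unequal")
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal covariances by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` is Brownian motion, `lambda = 0` a star phylogeny
#' (no shared history). The result stays positive semi-definite for
#' `lambda` in \[0, 1\] because it is a convex combination of `V` and
#' `diag(V)`.
#'
#' @param V Covariance matrix from [phylo_covariance()].
#' @param lambda Signal multiplier in \[0, 1\].
#' @return Transformed covariance matrix, same dimnames.
#' @export
lambda_scale <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1], got ", lambda)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

#' Ornstein-Uhlenbeck covariance for an ultrametric tree
#'
#' Hansen-style transform with the root at the optimum and variance
#' accumulating from zero: with tree depth T, shared path s_ij and
#' restraining force `alpha`,
#' \deqn{V_{ij} = \frac{1}{2\alpha} e^{-2\alpha (T - s_{ij})}
#'       \left(1 - e^{-2\alpha s_{ij}}\right).}
#' The stationary-scale parameter sigma^2 multiplies this matrix and is
#' fitted separately. As `alpha -> 0` the matrix tends to the Brownian
#' `s_ij`; as `alpha -> Inf` covariances vanish and the diagonal tends to
#' `1/(2 alpha)`.
#'
#' @param tree Ultrametric `"phylo"` object.
#' @param alpha Restraining force (> 0, per Myr).
#' @return Covariance matrix with the tree's tip order.
#' @export
ou_scale <- function(tree, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive value, got ", alpha)
  if (!is_ultrametric(tree))
    stop("OU transform assumes an ultrametric tree (equal root-to-tip depths)")
  S <- phylo_covariance(tree)
  T_depth <- mean(diag(S))
  V <- (1 / (2 * alpha)) * exp(-2 * alpha * (T_depth - S)) *
    (1 - exp(-2 * alpha * S))
  dimnames(V) <- dimnames(S)
  (V + t(V)) / 2
}

# Cholesky factor with a bounded jitter fallback. Matrices produced by
# lambda_scale/ou_scale are PSD in exact arithmetic but can lose strict
# positive definiteness to rounding; at most 1e-10 * trace is added to the
# diagonal before giving up.
chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  jit <- 1e-10 * sum(diag(V)) / nrow(V)
  ch <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  stop("covariance matrix is singular even after diagonal jitter of ",
       format(jit), "; check for duplicated tips or zero branch lengths")
}
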