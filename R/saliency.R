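#' Build the closed-loop affinity graph over superpixels
#'
#' Edges connect (a) spatially adjacent superpixels, (b) superpixels sharing
#' a common neighbor (two-hop closure), and (c) every pair of superpixels on
#' the image boundary, closing the border into a loop so the boundary prior
#' propagates around the frame. Edge weights decay exponentially with the
#' CIELAB distance between superpixel mean colors:
#' `w_ij = exp(-||c_i - c_j|| / sigma_c^2)`.
#'
#' @param sp A `"superpixels"` object.
#' @param sigma_c Color-affinity bandwidth on the `[0, 1]`-scaled CIELAB
#'   distance (default 0.1).
#' @return An object of class `"affinity_graph"`: list with symmetric
#'   zero-diagonal affinity matrix `W`, degree matrix `D`
#'   (`d_ii = sum_j w_ij`), the logical edge matrix `edges`, and `n`.
#' @export
build_closed_loop_graph <- function(sp, sigma_c = 0.1) {
  if (sigma_c <= 0) stop("sigma_c must be positive")
  if (sp$n < 2L) stop("graph needs at least 2 superpixels")
  n <- sp$n
  L <- sp$labels
  H <- nrow(L); W <- ncol(L)
  # adjacency from 8-neighborhood pixel pairs that straddle a label boundary
  pairs <- rbind(
    cbind(c(L[-H, ]), c(L[-1, ])),          # vertical
    cbind(c(L[, -W]), c(L[, -1])),          # horizontal
    cbind(c(L[-H, -W]), c(L[-1, -1])),      # diagonal \
    cbind(c(L[-H, -1]), c(L[-1, -W]))       # diagonal /
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE] + 1L
  A <- matrix(FALSE, n, n)
  A[pairs] <- TRUE
  A <- A | t(A)
  # two-hop closure: neighbors of neighbors
  A2 <- (A %*% A) > 0
  E <- A | A2
  # closed loop: all boundary superpixels mutually connected
  bd <- which(sp$is_boundary_top | sp$is_boundary_bottom |
                sp$is_boundary_left | sp$is_boundary_right)
  E[bd, bd] <- TRUE
  diag(E) <- FALSE
  dst <- as.matrix(stats::dist(sp$mean_color))
  Wm <- ifelse(E, exp(-dst / sigma_c^2), 0)
  diag(Wm) <- 0
  structure(list(W = Wm, D = diag(rowSums(Wm)), edges = E, n = n,
                 sigma_c = sigma_c),
            class = "affinity_graph")
}

#' Manifold ranking on an affinity graph
#'
#' Solves the regularized ranking system `f = (1 - alpha) (D - alpha W)^-1 y`
#' where `y` marks the query nodes. `alpha` balances the initial query
#' assignment against neighborhood propagation along the graph.
#'
#' @param graph An `"affinity_graph"`.
#' @param y Binary query indicator vector of length `graph$n`.
#' @param alpha Propagation parameter in (0, 1); default 0.99.
#' @param zero_diagonal If `TRUE`, the diagonal of the inverse propagation
#'   matrix is zeroed before applying `y`, so a query node's rank reflects
#'   only what it receives from others (a common variant); default `FALSE`.
#' @return List with `f` (raw ranking values) and `f_norm` (min-max
#'   normalized to `[0, 1]`; a constant `f` maps to all zeros with a
#'   warning).
#' @export
manifold_rank <- function(graph, y, alpha = 0.99, zero_diagonal = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(y) != graph$n) stop("query vector length must equal graph$n")
  if (!all(y %in% c(0, 1))) stop("query indicator must be binary")
  M <- graph$D - alpha * graph$W
  f <- tryCatch({
    if (zero_diagonal) {
      Ainv <- solve(M)
      diag(Ainv) <- 0
      (1 - alpha) * drop(Ainv %*% y)
    } else {
      (1 - alpha) * drop(solve(M, y))
    }
  }, error = function(e) {
    stop("manifold ranking system is numerically singular: ",
         conditionMessage(e))
  })
  list(f = f, f_norm = minmax_norm(f))
}

minmax_norm <- function(f) {
  rng <- range(f)
  if (diff(rng) == 0) {
    warning("constant ranking vector; normalizing to all zeros")
    return(rep(0, length(f)))
  }
  (f - rng[1]) / diff(rng)
}

#' Stage-one saliency from the boundary prior
#'
#' Ranks all superpixels against each image side's boundary superpixels as
#' background queries; each side's saliency is the complement of the
#' normalized ranking, `S_s(i) = 1 - f_norm(i)`, and the four side maps are
#' fused by a pointwise product `S = S_T * S_D * S_L * S_R`.
#'
#' @inheritParams manifold_rank
#' @param sp The `"superpixels"` object the graph was built from.
#' @return List of class `"saliency_field"` with per-superpixel `scores`
#'   in `[0, 1]` and the per-side maps in `sides`.
#' @export
boundary_stage_saliency <- function(graph, sp, alpha = 0.99) {
  sides <- list(top = sp$is_boundary_top, bottom = sp$is_boundary_bottom,
                left = sp$is_boundary_left, right = sp$is_boundary_right)
  maps <- lapply(names(sides), function(s) {
    q <- sides[[s]]
    if (!any(q)) stop("no boundary superpixels on side: ", s)
    r <- manifold_rank(graph, as.numeric(q), alpha)
    1 - r$f_norm
  })
  names(maps) <- names(sides)
  S <- maps$top * maps$bottom * maps$left * maps$right
  structure(list(scores = S, sides = maps, stage = 1L),
            class = "saliency_field")
}

#' Stage-two saliency from foreground queries
#'
#' Binarizes the stage-one map at its mean to pick foreground seed nodes,
#' then ranks all superpixels against those seeds; the final saliency is the
#' normalized ranking itself, which highlights the object uniformly.
#'
#' @inheritParams manifold_rank
#' @param stage1 The stage-one `"saliency_field"`.
#' @param zero_diagonal Passed to [manifold_rank()].
#' @return A `"saliency_field"` with final `scores` in `[0, 1]`.
#' @export
foreground_query_saliency <- function(graph, stage1, alpha = 0.99,
                                      zero_diagonal = FALSE) {
  S <- stage1$scores
  if (diff(range(S)) == 0)
    stop("degenerate stage-one map: constant scores admit no seed set")
  y <- as.numeric(S >= mean(S))
  r <- manifold_rank(graph, y, alpha, zero_diagonal = zero_diagonal)
  structure(list(scores = r$f_norm, seeds = y, stage = 2L),
            class = "saliency_field")
}

#' Upsample per-superpixel scores to a pixel raster
#'
#' @param field A `"saliency_field"` or bare numeric score vector.
#' @param sp The matching `"superpixels"` object.
#' @return Numeric matrix: each pixel carries its superpixel's score.
#' @export
upsample_saliency <- function(field, sp) {
  scores <- if (inherits(field, "saliency_field")) field$scores else field
  if (length(scores) != sp$n)
    stop("score vector length (", length(scores),
         ") does not match superpixel count (", sp$n, ")")
  matrix(scores[sp$labels + 1L], nrow = nrow(sp$labels))
}

#' Two-stage manifold-ranking saliency map
#'
#' Convenience wrapper running superpixel segmentation, closed-loop graph
#' construction, and both ranking stages; returns the pixel-level map.
#'
#' @inheritParams compute_superpixels
#' @inheritParams build_closed_loop_graph
#' @inheritParams manifold_rank
#' @param image Grayscale matrix or RGB array in `[0, 255]`.
#' @return List with `map` (pixel raster in `[0, 1]`), `stage1`, `stage2`
#'   (`"saliency_field"`s), `sp`, and `graph`.
#' @export
saliency_map <- function(image, n_target = 200, compactness = 10,
                         sigma_c = 0.1, alpha = 0.99, seed = 0L,
                         zero_diagonal = FALSE) {
  sp <- compute_superpixels(image, n_target = n_target,
                            compactness = compactness, seed = seed)
  graph <- build_closed_loop_graph(sp, sigma_c = sigma_c)
  s1 <- boundary_stage_saliency(graph, sp, alpha = alpha)
  s2 <- foreground_query_saliency(graph, s1, alpha = alpha,
                                  zero_diagonal = zero_diagonal)
  list(map = upsample_saliency(s2, sp), stage1 = s1, stage2 = s2,
       sp = sp, graph = graph)
}
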