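## Reconstruction of the latent partition from empirical pair correlations.
##
## The algorithm works level by level, from the largest limiting correlation
## down. At step u the pairs whose empirical correlation lies in the closed
## window around level u — and which do not share an index with any pair
## already claimed by an earlier level — form the edge set G_u; every pair
## touching an index seen in G_1..G_u is excluded from later levels. The
## classes are the connected components of the union of the G_u; under the
## typicality event controlled by the failure bound, they coincide with the
## latent groups.

#' Empirical pair correlations of a spin sample
#'
#' \eqn{\bar y_{ij} = n^{-1}\sum_t x_i^{(t)} x_j^{(t)}}, the only statistic
#' the detection algorithm consumes.
#'
#' @param sample A `"spin_sample"` or any numeric matrix with entries
#'   \eqn{\pm 1}, observations in rows.
#' @return An `N x N` symmetric matrix of class `"correlation_matrix"` with
#'   unit diagonal and attribute `n` (sample size).
#' @examples
#' x <- rbind(c(1, 1, -1), c(1, -1, -1))
#' empirical_correlations(x)
#' @export
empirical_correlations <- function(sample) {
  X <- unclass(as.matrix(sample))
  if (!all(X == 1 | X == -1)) stop("sample entries must be -1 or +1")
  n <- nrow(X)
  if (n < 1) stop("sample must contain at least one observation")
  C <- crossprod(X) / n
  dimnames(C) <- NULL
  attr(C, "n") <- n
  class(C) <- c("correlation_matrix", class(C))
  C
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Empirical correlation matrix:", nrow(x), "individuals, n =",
      attr(x, "n"), "observations\n")
  if (nrow(x) <= 12) print(round(unclass(x), 4))
  invisible(x)
}

## ---- union-find over individuals (path compression) -------------------

.uf_new <- function(n) seq_len(n)

.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Identify latent groups by iterative level-window clustering
#'
#' Implements the pair recursion exactly: with pairs
#' \eqn{A = \{(i,j): i \ne j\}} and levels \eqn{h_{(1)} > \dots > h_{(q)}},
#' \deqn{G_u = \{(i,j) \in A \setminus A_{u-1} :
#'   |\bar y_{ij} - h_{(u)}| \le w\},}
#' where \eqn{w} is the window half-width and \eqn{A_u} collects every pair
#' sharing an index with a pair in \eqn{G_1 \cup \dots \cup G_u}. Windows
#' are closed intervals; boundary ties are included. Classes are the
#' connected components (union-find) of \eqn{\cup_u G_u}; each class carries
#' the level index of its edges.
#'
#' Atypical samples are reported, not raised: `status` is
#' `"inconsistent_sample"` when a class has edges in two different windows,
#' when some individual remains unassigned after the last level, or when a
#' within-class pair lies outside its class's window. Diagnostics record the
#' per-pair window assignment and the unassigned individuals so batch
#' experiments can count failures.
#'
#' @param corr A `"correlation_matrix"` (or plain symmetric matrix of pair
#'   correlations).
#' @param spec A `"level_spec"` from [level_spec()], or a list with elements
#'   `levels` (decreasing) and `halfwidth` (scalar or one per level).
#' @return An object of class `"grouping_result"`: list with `membership`
#'   (length-`N` integer vector of class ids, `NA` when unassigned),
#'   `classes` (list of index vectors), `class_level` (window index per
#'   class), `status` (`"success"` or `"inconsistent_sample"`), and
#'   `diagnostics`.
#' @seealso [detect_communities()] for the one-call interface,
#'   [identify_groups_agnostic()] for the model-free variant.
#' @export
identify_groups <- function(corr, spec) {
  C <- unclass(as.matrix(corr))
  N <- nrow(C)
  if (ncol(C) != N) stop("'corr' must be square")
  levels <- spec$levels
  hw <- rep_len(spec$halfwidth, length(levels))
  q <- length(levels)
  if (q > 1 && any(diff(levels) >= 0)) stop("levels must be strictly decreasing")
  ## window overlap guard (closed windows must be disjoint)
  if (q > 1 && any(levels[-q] - hw[-q] <= levels[-1] + hw[-1])) {
    stop("consecutive level windows overlap; invalid level spec")
  }

  ut <- which(upper.tri(C), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]; y <- C[ut]
  ## window index of each pair (at most one, windows disjoint)
  win <- rep(NA_integer_, length(y))
  for (u in seq_len(q)) {
    inw <- abs(y - levels[u]) <= hw[u]
    win[inw & is.na(win)] <- u
  }

  parent <- .uf_new(N)
  touched <- rep(FALSE, N)       # indices incident to an accepted edge
  edge_level <- rep(NA_integer_, length(y))
  for (u in seq_len(q)) {
    gu <- which(win == u & !touched[i] & !touched[j])
    edge_level[gu] <- u
    if (length(gu)) {
      for (e in gu) parent <- .uf_union(parent, i[e], j[e])
      touched[unique(c(i[gu], j[gu]))] <- TRUE
    }
  }

  roots <- vapply(seq_len(N), function(k) .uf_find(parent, k), integer(1))
  assigned <- touched
  status <- "success"
  notes <- character(0)

  if (!all(assigned)) {
    status <- "inconsistent_sample"
    notes <- c(notes, paste0(sum(!assigned), " individual(s) unassigned"))
  }

  ## classes over assigned individuals only
  cls_ids <- unique(roots[assigned])
  classes <- lapply(cls_ids, function(r) which(roots == r & assigned))
  ## order classes by their level (top level first), then by first member
  class_level <- vapply(seq_along(classes), function(ci) {
    members <- classes[[ci]]
    lv <- unique(edge_level[!is.na(edge_level) &
                              i %in% members & j %in% members])
    if (length(lv) > 1) NA_integer_ else lv
  }, integer(1))
  if (anyNA(class_level) && length(classes)) {
    status <- "inconsistent_sample"
    notes <- c(notes, "a class has edges in two different windows")
  }
  ord <- order(ifelse(is.na(class_level), Inf, class_level),
               vapply(classes, min, integer(1)))
  classes <- classes[ord]
  class_level <- class_level[ord]

  ## every within-class pair must sit in the class's window
  for (ci in seq_along(classes)) {
    members <- classes[[ci]]
    if (length(members) < 2 || is.na(class_level[ci])) next
    inside <- i %in% members & j %in% members
    bad <- inside & (is.na(win) | win != class_level[ci])
    if (any(bad)) {
      status <- "inconsistent_sample"
      notes <- c(notes, sprintf(
        "class %d: %d within-class pair(s) outside its window", ci, sum(bad)))
    }
  }

  membership <- rep(NA_integer_, N)
  for (ci in seq_along(classes)) membership[classes[[ci]]] <- ci

  structure(
    list(membership = membership, classes = classes,
         class_level = class_level, status = status,
         labels_hat = NULL,
         diagnostics = list(
           pair_window = data.frame(i = i, j = j, ybar = y, window = win),
           unassigned = which(!assigned),
           notes = notes,
           levels = levels, halfwidth = hw)),
    class = "grouping_result"
  )
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("Community detection result:", length(x$classes), "class(es), status:",
      x$status, "\n")
  for (ci in seq_along(x$classes)) {
    lab <- if (!is.null(x$labels_hat)) {
      paste0(", label ", x$labels_hat[ci],
             if (isTRUE(x$label_ambiguous[ci])) " (ambiguous)" else "")
    } else ""
    cat(sprintf("  class %d (level %s%s): %d individual(s)\n",
                ci, format(x$class_level[ci]), lab, length(x$classes[[ci]])))
  }
  if (length(x$diagnostics$notes)) {
    cat("  notes:", paste(x$diagnostics$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.grouping_result <- function(object, ...) {
  cat("Classes:", length(object$classes), " status:", object$status, "\n")
  sizes <- vapply(object$classes, length, integer(1))
  print(data.frame(class = seq_along(sizes), level = object$class_level,
                   size = sizes,
                   label_hat = if (is.null(object$labels_hat)) NA
                               else object$labels_hat))
  invisible(object)
}

#' Map recovered classes to model group indices
#'
#' The window recursion recovers the partition; which latent group each class
#' corresponds to is resolvable when the correlation levels of the groups
#' differ (each level then names its group) or, within a shared level, when
#' the group sizes differ (classes are matched to sizes). When several groups
#' share both their level and their size the model is symmetric under their
#' exchange, so a valid labelling is returned with the affected classes
#' flagged ambiguous.
#'
#' @param result A successful `"grouping_result"`.
#' @param spec The `"level_spec"` used for detection (its `groups_at_level`
#'   carries the level-to-group map).
#' @param sizes Optional vector of model group sizes, used to disambiguate
#'   groups sharing a level.
#' @return `result` with `labels_hat` (group index per class) and
#'   `label_ambiguous` (logical per class) filled in.
#' @export
label_classes <- function(result, spec, sizes = NULL) {
  stopifnot(inherits(result, "grouping_result"))
  if (result$status != "success") {
    stop("labels can only be assigned to a successful grouping")
  }
  groups_at_level <- spec$groups_at_level
  M <- length(unlist(groups_at_level))
  if (length(result$classes) != M) {
    stop("class count (", length(result$classes),
         ") differs from model group count (", M,
         "): detection failed upstream")
  }
  labels_hat <- rep(NA_integer_, length(result$classes))
  ambiguous <- rep(FALSE, length(result$classes))
  for (u in seq_along(groups_at_level)) {
    cls_u <- which(result$class_level == u)
    grp_u <- groups_at_level[[u]]
    if (length(cls_u) != length(grp_u)) {
      stop("level ", u, ": ", length(cls_u), " class(es) but ",
           length(grp_u), " group(s); detection failed upstream")
    }
    if (length(grp_u) == 1L) {
      labels_hat[cls_u] <- grp_u
    } else if (!is.null(sizes)) {
      cl_sizes <- vapply(result$classes[cls_u], length, integer(1))
      remaining <- grp_u
      level_ambiguous <- FALSE
      for (k in seq_along(cls_u)) {
        match_g <- remaining[sizes[remaining] == cl_sizes[k]]
        if (length(match_g) == 1L) {
          labels_hat[cls_u[k]] <- match_g
          remaining <- setdiff(remaining, match_g)
        } else if (length(match_g) > 1L) {
          labels_hat[cls_u[k]] <- match_g[1]
          level_ambiguous <- TRUE
          remaining <- setdiff(remaining, match_g[1])
        } else {
          stop("no group size matches class of size ", cl_sizes[k],
               " at level ", u)
        }
      }
      if (level_ambiguous) ambiguous[cls_u] <- TRUE
    } else {
      labels_hat[cls_u] <- grp_u[seq_along(cls_u)]
      ambiguous[cls_u] <- TRUE
    }
  }
  result$labels_hat <- labels_hat
  result$label_ambiguous <- ambiguous
  result
}

#' Model-free band detection of latent groups
#'
#' Heuristic extension beyond the guaranteed regime-based algorithm: the
#' \eqn{N(N-1)/2} empirical correlations are sorted and split at every gap
#' larger than `min_gap` into bands; the band centres and half-ranges then
#' play the role of levels and windows in the same recursion as
#' [identify_groups()]. A banding is admissible when the recursion succeeds
#' and every class at the top bands has cardinality compatible with a
#' \eqn{k(k-1)/2} clique of correlations. When `min_gap` is not supplied it
#' is chosen automatically: if the largest gap between consecutive sorted
#' correlations exceeds a quarter of their total range, bands are cut at
#' every gap within a factor 3 of the largest; otherwise the values are
#' treated as one structureless band (pure sampling noise has uniform-ish
#' spacings and never qualifies). If no admissible multi-band split exists a
#' single class is returned. No recovery guarantee attaches to this mode.
#'
#' @param corr A correlation matrix as in [identify_groups()].
#' @param min_gap Minimum gap between consecutive sorted correlations at
#'   which to cut bands; `NULL` for the automatic choice.
#' @return A `"grouping_result"`, with the chosen bands in `diagnostics`.
#' @export
identify_groups_agnostic <- function(corr, min_gap = NULL) {
  C <- unclass(as.matrix(corr))
  N <- nrow(C)
  y <- sort(C[upper.tri(C)], decreasing = TRUE)
  auto <- is.null(min_gap)
  if (auto) {
    gaps <- -diff(y)
    rng <- max(y) - min(y)
    ## a split is only significant when the dominant gap is a sizeable
    ## fraction of the whole correlation range; uniform-ish spacings (pure
    ## sampling noise) never qualify, so noise collapses to a single band
    if (!length(gaps) || max(gaps) <= rng / 4) {
      min_gap <- Inf
    } else {
      min_gap <- max(gaps) / 3   # capture every gap comparable to the largest
    }
  }
  bands <- .cut_bands(y, min_gap)
  res <- .bands_to_grouping(C, bands)
  if (!is.null(res) && res$status == "success") {
    res$diagnostics$bands <- bands
    res$diagnostics$min_gap <- min_gap
    return(res)
  }
  if (auto) {
    ## no admissible split: treat as structureless, one band spanning all
    bands <- .cut_bands(y, Inf)
    res <- .bands_to_grouping(C, bands)
    res$diagnostics$bands <- bands
    res$diagnostics$min_gap <- Inf
    if (res$status != "success") {
      stop("no admissible banding found for the correlation values")
    }
    return(res)
  }
  if (is.null(res)) stop("no admissible banding found for the correlation values")
  res$diagnostics$bands <- bands
  res$diagnostics$min_gap <- min_gap
  res
}

.cut_bands <- function(y_desc, min_gap) {
  cuts <- if (is.finite(min_gap)) which(-diff(y_desc) > min_gap) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(y_desc))
  lapply(seq_along(starts), function(b) y_desc[starts[b]:ends[b]])
}

.bands_to_grouping <- function(C, bands) {
  centers <- vapply(bands, function(b) (max(b) + min(b)) / 2, numeric(1))
  halfr <- vapply(bands, function(b) (max(b) - min(b)) / 2, numeric(1))
  ## pad half-ranges so zero-width bands still capture their boundary values,
  ## without letting consecutive windows touch
  if (length(centers) > 1) {
    edge_gap <- min(vapply(seq_len(length(bands) - 1), function(u) {
      min(bands[[u]]) - max(bands[[u + 1]])
    }, numeric(1)))
    pad <- edge_gap / 4
  } else {
    pad <- max(1e-12, max(halfr) * 1e-6)
  }
  spec <- list(levels = centers, halfwidth = halfr + pad)
  if (length(centers) > 1 &&
      any(centers[-length(centers)] - spec$halfwidth[-length(centers)] <=
            centers[-1] + spec$halfwidth[-1])) {
    return(NULL)
  }
  res <- identify_groups(C, spec)
  if (res$status == "success") {
    ## record the clique-cardinality bookkeeping: a class of size k accounts
    ## for k(k-1)/2 of the pairs in its band (the window checks inside
    ## identify_groups enforce this; bands holding only excluded cross-group
    ## pairs contribute no class)
    sizes <- vapply(res$classes, length, integer(1))
    res$diagnostics$band_summary <- data.frame(
      band = seq_along(bands),
      n_pairs = vapply(bands, length, integer(1)),
      n_clique_pairs = vapply(seq_along(bands), function(u) {
        as.integer(sum(sizes[res$class_level == u] *
                         (sizes[res$class_level == u] - 1) / 2))
      }, integer(1)))
  }
  res
}

#' Detect communities in a sample of binary configurations
#'
#' One-call interface: computes empirical correlations, derives the level
#' specification from the model's regime theory (high temperature: the
#' size-adjusted inverse of \eqn{H = J^{-1} - I}; low temperature: the
#' `Z`-vector Gram matrix of the free-energy minima), runs the window
#' recursion, and labels the classes. With `model = NULL` the model-free
#' band heuristic is used instead.
#'
#' @param sample A `"spin_sample"` or \eqn{\pm 1} matrix (rows =
#'   observations), or a precomputed `"correlation_matrix"`.
#' @param model The generating `"block_spin"` model (or `NULL` for the
#'   agnostic mode).
#' @param regime `"auto"` (classify from `J`), `"high"` or `"low"`.
#' @param ... Passed to [identify_groups_agnostic()] when `model` is `NULL`.
#' @return A `"grouping_result"` with labels when a model is supplied.
#' @examples
#' m <- block_spin(c(6, 6), matrix(c(1.5, -0.1, -0.1, 1.5), 2, 2))
#' x <- draw_sample(m, 4000, seed = 7)
#' detect_communities(x, m)
#' @export
detect_communities <- function(sample, model = NULL,
                               regime = c("auto", "high", "low"), ...) {
  regime <- match.arg(regime)
  corr <- if (inherits(sample, "correlation_matrix")) sample
          else empirical_correlations(sample)
  if (is.null(model)) {
    return(identify_groups_agnostic(corr, ...))
  }
  stopifnot(inherits(model, "block_spin"))
  if (regime == "auto") regime <- spin_regime(model)$regime
  if (regime == "critical") {
    stop("detection is not supported in the critical regime")
  }
  spec <- if (regime == "high") {
    level_spec(pair_limit_high(model))
  } else {
    level_spec(z_vectors(model, find_minima(model, compute_z = FALSE)))
  }
  res <- identify_groups(corr, spec)
  if (res$status == "success" &&
      length(res$classes) == model$M) {
    res <- label_classes(res, spec, sizes = model$sizes)
  }
  res
}
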