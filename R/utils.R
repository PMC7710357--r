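#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv
#' @importFrom graphics lines
"_PACKAGE"

## Small shared helpers. Coordinates are micrometres throughout; the pixel
## grid appears only when rendering images and for pixel-denominated
## thresholds (converted through `pixel_size`). Frames are 0-based integers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_config("configuration error: '%s' must be a probability in [0, 1]", name)
  p
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_config("configuration error: '%s' must be a non-negative number", name)
  x
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config("configuration error: '%s' must be a positive number", name)
  x
}

#' One-to-one minimal-distance point matching
#'
#' Matches rows of `a` to rows of `b` one-to-one so that (i) the number of
#' matched pairs with distance at or below `threshold` is maximal and (ii)
#' among such matchings the total distance is minimal. The bipartite graph of
#' admissible pairs is split into connected components; each component is
#' solved by exact enumeration when small enough, otherwise by a
#' distance-sorted greedy pass (`method = "greedy"` forces greedy matching
#' everywhere, useful for sensitivity checks). Ties are broken towards lower
#' row indices.
#'
#' @param a,b two-column numeric matrices (x, y) in micrometres.
#' @param threshold maximum pair distance in micrometres.
#' @param method `"optimal"` (component-wise exact) or `"greedy"`.
#' @param max_exact largest component side enumerated exactly.
#' @return integer matrix with columns `a`, `b` (row indices) and a
#'   `dist` attribute of matched distances.
#' @export
match_points <- function(a, b, threshold, method = c("optimal", "greedy"),
                         max_exact = 8L) {
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  empty <- cbind(a = integer(0), b = integer(0))
  if (na == 0L || nb == 0L) return(structure(empty, dist = numeric(0)))
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  adm <- d <= threshold
  if (!any(adm)) return(structure(empty, dist = numeric(0)))

  if (method == "greedy") {
    pairs <- greedy_match(d, adm)
  } else {
    comp <- bipartite_components(adm)
    pairs <- empty
    for (cc in comp) {
      ai <- cc$a; bi <- cc$b
      if (length(ai) == 1L && length(bi) == 1L) {
        pairs <- rbind(pairs, cbind(a = ai, b = bi))
      } else if (min(length(ai), length(bi)) <= max_exact &&
                 max(length(ai), length(bi)) <= 2L * max_exact) {
        sub <- exact_match(d[ai, bi, drop = FALSE], adm[ai, bi, drop = FALSE])
        if (nrow(sub)) pairs <- rbind(pairs, cbind(a = ai[sub[, 1]], b = bi[sub[, 2]]))
      } else {
        sub <- greedy_match(d[ai, bi, drop = FALSE], adm[ai, bi, drop = FALSE])
        if (nrow(sub)) pairs <- rbind(pairs, cbind(a = ai[sub[, 1]], b = bi[sub[, 2]]))
      }
    }
    if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(pairs, dist = d[pairs])
}

## connected components of the bipartite admissibility graph
bipartite_components <- function(adm) {
  na <- nrow(adm); nb <- ncol(adm)
  seen_a <- logical(na); seen_b <- logical(nb)
  comps <- list()
  for (s in seq_len(na)) {
    if (seen_a[s] || !any(adm[s, ])) next
    qa <- s; ca <- integer(0); cb <- integer(0)
    seen_a[s] <- TRUE
    qb <- integer(0)
    repeat {
      if (length(qa)) {
        i <- qa[1]; qa <- qa[-1]; ca <- c(ca, i)
        nbrs <- which(adm[i, ] & !seen_b)
        seen_b[nbrs] <- TRUE; qb <- c(qb, nbrs)
      } else if (length(qb)) {
        j <- qb[1]; qb <- qb[-1]; cb <- c(cb, j)
        nbrs <- which(adm[, j] & !seen_a)
        seen_a[nbrs] <- TRUE; qa <- c(qa, nbrs)
      } else break
    }
    comps[[length(comps) + 1L]] <- list(a = sort(ca), b = sort(cb))
  }
  comps
}

## exact assignment on one component: maximize pair count, then minimize
## total distance; recursion over rows of the smaller side
exact_match <- function(d, adm) {
  na <- nrow(d); nb <- ncol(d)
  flip <- nb < na
  if (flip) { d <- t(d); adm <- t(adm); tmp <- na; na <- nb; nb <- tmp }
  best <- list(count = -1L, total = Inf, assign = integer(na))
  assign <- integer(na)      # 0 = unmatched
  used <- logical(nb)
  recurse <- function(i, count, total) {
    if (count + (na - i + 1L) < best$count) return()
    if (i > na) {
      if (count > best$count || (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total, assign = assign)
      }
      return()
    }
    for (j in seq_len(nb)) {
      if (adm[i, j] && !used[j]) {
        used[j] <<- TRUE; assign[i] <<- j
        recurse(i + 1L, count + 1L, total + d[i, j])
        used[j] <<- FALSE; assign[i] <<- 0L
      }
    }
    recurse(i + 1L, count, total)   # leave row i unmatched
  }
  recurse(1L, 0L, 0)
  ii <- which(best$assign > 0L)
  out <- cbind(ii, best$assign[ii])
  if (flip) out <- out[, 2:1, drop = FALSE]
  colnames(out) <- c("a", "b")
  out
}

greedy_match <- function(d, adm) {
  ord <- order(d)
  ord <- ord[adm[ord]]
  na <- nrow(d); nb <- ncol(d)
  ua <- logical(na); ub <- logical(nb)
  res <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  for (k in ord) {
    i <- ((k - 1L) %% na) + 1L
    j <- ((k - 1L) %/% na) + 1L
    if (!ua[i] && !ub[j]) {
      ua[i] <- TRUE; ub[j] <- TRUE
      res <- rbind(res, cbind(a = i, b = j))
    }
  }
  if (nrow(res)) res[order(res[, 1]), , drop = FALSE] else res
}

## unit vector helper; zero vectors stay zero
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}
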