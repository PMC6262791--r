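# Independent oracles used to validate the morphological core and the
# statistics. These deliberately use different algorithms from the package:
# the reconstruction oracle works by threshold decomposition (level sets),
# maxima are found by brute plateau search, and Fisher's exact test is a
# full hypergeometric enumeration.

# neighbor list (linear indices) for every voxel of a small grid
oracle_neighbor_list <- function(d, connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- switch(as.character(connectivity),
                 "6"  = offs[rowSums(abs(offs)) == 1, ],
                 "18" = offs[rowSums(abs(offs)) <= 2, ],
                 "26" = offs)
  co <- arrayInd(seq_len(prod(d)), d)
  lapply(seq_len(prod(d)), function(v) {
    nb <- sweep(as.matrix(offs), 2, co[v, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
  })
}

# scalar stack-based flood labeling of a logical vector given a neighbor list
oracle_flood_label <- function(maskvec, nb) {
  labs <- integer(length(maskvec))
  nl <- 0L
  for (s in seq_along(maskvec)) {
    if (!maskvec[s] || labs[s] != 0L) next
    nl <- nl + 1L
    labs[s] <- nl
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      w <- nb[[v]]
      w <- w[maskvec[w] & labs[w] == 0L]
      if (length(w)) {
        labs[w] <- nl
        stack <- c(stack, w)
      }
    }
  }
  labs
}

# geodesic reconstruction of (f - h) under f by threshold decomposition:
# R(x) = max over levels t of min(t, max marker over the component of
# {f >= t} containing x). Exact for integer-valued grids.
oracle_reconstruct <- function(f, h, connectivity, nb = NULL) {
  d <- dim(f)
  if (is.null(nb)) nb <- oracle_neighbor_list(d, connectivity)
  fv <- as.vector(f)
  mv <- fv - h
  R <- rep(-Inf, length(fv))
  for (t in sort(unique(fv))) {
    maskvec <- fv >= t
    labs <- oracle_flood_label(maskvec, nb)
    mx <- tapply(mv[maskvec], labs[maskvec], max)
    vals <- rep(-Inf, length(fv))
    vals[maskvec] <- pmin(t, as.numeric(mx[as.character(labs[maskvec])]))
    R <- pmax(R, vals)
  }
  array(R, d)
}

# brute-force regional maxima: start from voxels with no strictly higher
# neighbor, then repeatedly drop candidates whose plateau continues into a
# non-candidate voxel of equal value
oracle_regional_maxima <- function(g, connectivity, nb = NULL) {
  d <- dim(g)
  if (is.null(nb)) nb <- oracle_neighbor_list(d, connectivity)
  gv <- as.vector(g)
  cand <- vapply(seq_along(gv), function(v) all(gv[nb[[v]]] <= gv[v]), logical(1))
  repeat {
    drop <- vapply(which(cand), function(v)
      any(!cand[nb[[v]]] & gv[nb[[v]]] == gv[v]), logical(1))
    if (!any(drop)) break
    cand[which(cand)[drop]] <- FALSE
  }
  labs <- oracle_flood_label(cand, nb)
  list(mask = array(cand, d), labels = array(labs, d), n = max(labs))
}

oracle_extended_maxima <- function(f, h, connectivity) {
  nb <- oracle_neighbor_list(dim(f), connectivity)
  R <- oracle_reconstruct(f, h, connectivity, nb)
  oracle_regional_maxima(R, connectivity, nb)
}

# do two labelings describe the same partition of the same mask?
same_partition <- function(lab_a, lab_b) {
  if (!identical(lab_a > 0, lab_b > 0)) return(FALSE)
  sel <- lab_a > 0
  a <- lab_a[sel]; b <- lab_b[sel]
  length(unique(a)) == length(unique(paste(a, b))) &&
    length(unique(b)) == length(unique(paste(a, b)))
}

random_grid <- function(seed, max_dim = c(12, 12, 6), vmax = 20) {
  set.seed(seed)
  d <- c(sample(4:max_dim[1], 1), sample(4:max_dim[2], 1), sample(3:max_dim[3], 1))
  array(sample(0:vmax, prod(d), replace = TRUE), d)
}

# full hypergeometric enumeration of Fisher's two-sided p (probability-mass
# rule) for a 2x2 table
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  p0 <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# match detected centroids to planted truth within `radius` um (greedy
# nearest-pair, one-to-one); returns matched index pairs
match_centroids <- function(detected, truth, radius) {
  if (nrow(detected) == 0 || nrow(truth) == 0)
    return(data.frame(det = integer(0), tru = integer(0)))
  d <- sqrt(outer(detected$x, truth$x, "-")^2 +
            outer(detected$y, truth$y, "-")^2 +
            outer(detected$z, truth$z, "-")^2)
  pairs <- data.frame(det = integer(0), tru = integer(0))
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > radius) break
    i <- (m - 1) %% nrow(d) + 1
    j <- (m - 1) %/% nrow(d) + 1
    pairs <- rbind(pairs, data.frame(det = i, tru = j))
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  pairs
}

# axial angular distance in degrees (orientations modulo 180)
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
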