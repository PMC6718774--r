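# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they test.

# symmetric reflection of possibly out-of-range indices into 1..n
oracle_reflect <- function(i, n) {
  repeat {
    low <- i < 1L
    high <- i > n
    if (!any(low) && !any(high)) return(i)
    i[low] <- 1L - i[low]
    i[high] <- 2L * n + 1L - i[high]
  }
}

# direct (non-separable) 2-D Gaussian convolution with reflect border
oracle_conv2 <- function(frame, sigma) {
  r <- ceiling(3 * sigma)
  x <- seq.int(-r, r)
  w1 <- exp(-x^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  nr <- nrow(frame)
  nc <- ncol(frame)
  padded <- frame[oracle_reflect(seq.int(1L - r, nr + r), nr),
                  oracle_reflect(seq.int(1L - r, nc + r), nc)]
  out <- matrix(0, nr, nc)
  for (u in seq_len(2L * r + 1L)) {
    for (v in seq_len(2L * r + 1L)) {
      out <- out + w2[u, v] *
        padded[u:(u + nr - 1L), v:(v + nc - 1L)]
    }
  }
  out
}

# flood-fill labeling by iterated minimum-label propagation to a fixed point
oracle_flood_labels <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)  # unique provisional labels
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    do.call(c, lapply(-1:1, function(dr) lapply(-1:1, function(dc) c(dr, dc))))
  }
  offs <- Filter(function(o) any(o != 0), offs)
  repeat {
    cand <- lab
    for (o in offs) cand <- pmin(cand, shift(lab, o[1], o[2]))
    cand[!mask] <- Inf
    if (identical(cand, lab)) break
    lab <- cand
  }
  lab[!mask] <- 0
  lab
}

# a labeling as a canonical partition: sorted list of sorted pixel-index sets
as_partition <- function(lab) {
  fg <- which(lab > 0 & is.finite(lab))
  parts <- split(fg, lab[fg])
  parts <- lapply(parts, function(x) as.integer(sort(unname(x))))
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

roi_set_partition <- function(rois) {
  d <- caltrace::frame_dim(rois)
  parts <- lapply(rois$pixels, function(p) {
    as.integer(sort(unname((p[, 2] - 1L) * d[1] + p[, 1])))
  })
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# maximum spike matching by exhaustive assignment (small inputs only)
oracle_spike_match <- function(detected, truth, tol) {
  if (length(detected) == 0L || length(truth) == 0L) return(0L)
  best <- 0L
  recurse <- function(ti, used) {
    if (ti > length(truth)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    ok <- which(!used & abs(detected - truth[ti]) <= tol)
    for (j in ok) {
      used[j] <- TRUE
      recurse(ti + 1L, used)
      used[j] <- FALSE
    }
    recurse(ti + 1L, used)
  }
  recurse(1L, logical(length(detected)))
  best
}

# random roi_set built from a Bernoulli mask (helper for matching tests)
random_roi_set <- function(nr, nc, p, connectivity = 4L) {
  mask <- matrix(runif(nr * nc) < p, nr, nc)
  caltrace::label_components(mask, connectivity = connectivity, min_size_px = 1L)
}
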