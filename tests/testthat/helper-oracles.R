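# Brute-force oracles, deliberately written as literal per-pixel /
# per-region loops, independent of the vectorized implementation paths.

# Literal evaluation of the (weighted) pixel-wise fusion rule at every
# pixel: background iff all weighted confidences fall below the gate,
# otherwise the class of the maximum (first max = lowest class id).
oracle_fuse_pixel <- function(maps_list, class_ids, weights = NULL,
                              threshold = 0.5) {
  h <- nrow(maps_list[[1L]])
  w <- ncol(maps_list[[1L]])
  k <- length(maps_list)
  if (is.null(weights)) weights <- rep(1, k)
  out <- matrix(0L, h, w)
  v <- numeric(k)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      for (i in seq_len(k)) v[i] <- weights[i] * maps_list[[i]][y, x]
      if (any(v >= threshold)) out[y, x] <- class_ids[which.max(v)]
    }
  }
  out
}

# Breadth-first flood fill over the foreground; returns a list of linear
# (column-major) pixel index vectors, one per component.
oracle_components <- function(fg, connectivity = 8) {
  h <- nrow(fg)
  w <- ncol(fg)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (start in which(fg)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0L) {
      cur <- queue[1L]
      queue <- queue[-1L]
      members <- c(members, cur)
      cy <- ((cur - 1L) %% h) + 1L
      cx <- ((cur - 1L) %/% h) + 1L
      for (o in offs) {
        ny <- cy + o[1L]
        nx <- cx + o[2L]
        if (ny < 1L || ny > h || nx < 1L || nx > w) next
        ni <- (nx - 1L) * h + ny
        if (fg[ni] && !seen[ni]) {
          seen[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

oracle_majority <- function(vals, class_ids) {
  counts <- vapply(class_ids, function(cc) sum(vals == cc), integer(1))
  class_ids[which.max(counts)]
}

# Staged brute force for the region-based operators: literal pixel rule,
# flood-fill components, per-region label histogram argmax.
oracle_fuse_region <- function(maps_list, class_ids, weights = NULL,
                               threshold = 0.5, connectivity = 8) {
  px <- oracle_fuse_pixel(maps_list, class_ids, weights, threshold)
  for (comp in oracle_components(px != 0L, connectivity)) {
    px[comp] <- oracle_majority(px[comp], class_ids)
  }
  px
}

rand_maps <- function(h = 64, w = 64, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(k), function(i) matrix(runif(h * w), h, w))
}

rand_label_map <- function(h = 32, w = 32, class_ids = 1:3, seed = NULL,
                           p_bg = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(c(0L, class_ids), h * w, replace = TRUE,
                prob = c(p_bg, rep((1 - p_bg) / length(class_ids),
                                   length(class_ids)))),
         h, w)
}
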