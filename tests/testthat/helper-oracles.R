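# Independent oracles, implemented with different algorithms (and different
# code paths) from the package internals they check.

# H0 oracle: finite Rips H0 deaths are exactly the single-linkage merge
# heights (the MST edge lengths), computed here via stats::hclust.
oracle_h0_deaths <- function(points) {
  sort(stats::hclust(stats::dist(points), method = "single")$height)
}

# Full persistence oracle by textbook boundary-matrix reduction over GF(2),
# with every simplex (vertex, edge, triangle) as an explicit column. Only
# feasible for small clouds (<= ~25 points). Uses the same enclosing-radius
# cut-off convention as rips_persistence so the finite diagrams coincide.
oracle_rips_diagram <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  threshold <- min(apply(D, 1L, max))

  vals <- rep(0, n)
  dims <- rep(0L, n)
  bounds <- rep(list(integer(0)), n)

  edge_id <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] <= threshold) {
        vals <- c(vals, D[i, j])
        dims <- c(dims, 1L)
        bounds <- c(bounds, list(c(i, j)))
        edge_id[i, j] <- length(vals)
      }
    }
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        if (D[i, j] > threshold) next
        for (k in (j + 1L):n) {
          m <- max(D[i, j], D[i, k], D[j, k])
          if (m <= threshold) {
            vals <- c(vals, m)
            dims <- c(dims, 2L)
            bounds <- c(bounds, list(sort(c(edge_id[i, j], edge_id[i, k],
                                            edge_id[j, k]))))
          }
        }
      }
    }
  }

  # filtration order: by value, then faces before cofaces
  ord <- order(vals, dims)
  pos <- integer(length(ord))
  pos[ord] <- seq_along(ord)

  symdiff <- function(a, b) {
    s <- c(a, b)
    sort(s[!(duplicated(s) | duplicated(s, fromLast = TRUE))])
  }

  m <- length(ord)
  low_owner <- integer(m)
  stored <- vector("list", m)
  pairs <- matrix(0L, 0L, 2L)
  for (jj in seq_len(m)) {
    sid <- ord[jj]
    col <- sort(pos[bounds[[sid]]])
    while (length(col) > 0L && low_owner[max(col)] > 0L) {
      col <- symdiff(col, stored[[low_owner[max(col)]]])
    }
    if (length(col) > 0L) {
      low_owner[max(col)] <- jj
      stored[[jj]] <- col
      pairs <- rbind(pairs, c(max(col), jj))
    }
  }

  h0 <- numeric(0)
  h1 <- matrix(0, 0L, 2L, dimnames = list(NULL, c("birth", "death")))
  for (r in seq_len(nrow(pairs))) {
    i_sid <- ord[pairs[r, 1L]]
    j_sid <- ord[pairs[r, 2L]]
    if (dims[i_sid] == 0L && vals[j_sid] > 0) {
      h0 <- c(h0, vals[j_sid])
    } else if (dims[i_sid] == 1L && vals[j_sid] > vals[i_sid]) {
      h1 <- rbind(h1, c(vals[i_sid], vals[j_sid]))
    }
  }
  list(h0_deaths = sort(h0),
       h1 = h1[order(h1[, 1L], h1[, 2L]), , drop = FALSE],
       threshold = threshold)
}

# Brute-force 90%-containment radius over the grid 100, 110, 120, ...
oracle_radius <- function(points, m, start = 100, step = 10, coverage = 0.9) {
  d <- sqrt(rowSums(sweep(as.matrix(points), 2L, m)^2))
  grid <- seq(start, max(start, max(d)) + step, by = step)
  grid[which(vapply(grid, function(r) mean(d <= r) >= coverage,
                    logical(1)))[1L]]
}

# Count of strict 8-neighbourhood local maxima of a height matrix.
count_local_maxima <- function(z) {
  nr <- nrow(z)
  nc <- ncol(z)
  count <- 0L
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      nb <- z[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (z[i, j] > max(nb[-5L])) count <- count + 1L
    }
  }
  count
}

# BFS connected component over an edge list, independent of igraph.
oracle_component <- function(edges, n, start) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]
    b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  which(seen)
}

# Build a persistence_diagram object from explicit bars, for closed-form
# checks of the diagram summaries.
make_diagram <- function(dimension, birth, death) {
  dg <- tibble::tibble(dimension = as.integer(dimension),
                       birth = as.numeric(birth), death = as.numeric(death))
  structure(dg, class = c("persistence_diagram", class(dg)),
            n_essential_h0 = 1L, n_essential_h1 = 0L,
            max_filtration = max(death), n_points = NA_integer_)
}
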