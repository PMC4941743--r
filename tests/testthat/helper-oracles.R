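# Independent brute-force oracles, deliberately naive implementations
# kept separate from the package's code paths.

# exhaustive cell scan: count grid cells containing any foreground
oracle_count_boxes <- function(trace, size, origin = c(0L, 0L)) {
  px <- trace$pixels
  nr <- nrow(px); nc <- ncol(px)
  starts <- function(origin, n) {
    st <- seq(origin + 1L, n, by = size)
    if (origin > 0L) st <- c(origin + 1L - size, st)  # partial cell before origin
    st
  }
  count <- 0L
  for (r0 in starts(origin[1], nr)) for (c0 in starts(origin[2], nc)) {
    rs <- max(1L, r0):min(nr, r0 + size - 1L)
    cs <- max(1L, c0):min(nc, c0 + size - 1L)
    if (any(px[rs, cs] == 1L)) count <- count + 1L
  }
  count
}

# pixelwise neighbourhood scan for border extraction
oracle_border <- function(trace, connectivity = 8) {
  px <- trace$pixels
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (px[r, c] != 1L) next
    for (k in seq_len(nrow(nbrs))) {
      rr <- r + nbrs$dr[k]; cc <- c + nbrs$dc[k]
      bg <- rr < 1 || rr > nr || cc < 1 || cc > nc || px[rr, cc] == 0L
      if (bg) { out[r, c] <- 1L; break }
    }
  }
  out
}

# simple-regression slope/intercept via explicit normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# shared root-to-MRCA path length for every tip pair, walked node by node
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  elen <- function(node) tree$edge.length[match(node, tree$edge[, 2])]
  path_nodes <- lapply(seq_len(n), function(i) ape::nodepath(tree, root, i))
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pi <- path_nodes[[i]]; pj <- path_nodes[[j]]
    shared <- intersect(pi[-1], pj[-1])   # nodes below the root
    V[i, j] <- sum(vapply(shared, elen, numeric(1)))
  }
  V
}

# sorted tip-sets of all non-trivial bipartitions (topology fingerprint)
oracle_bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  internal <- (n + 2L):(n + tree$Nnode)
  if (n + tree$Nnode < n + 2L) return(character(0))
  sets <- lapply(internal, function(v)
    sort(ape::extract.clade(tree, v)$tip.label))
  sort(vapply(sets, paste, character(1), collapse = "|"))
}

rand_trace <- function(seed, nr = 32, nc = 32, p = 0.15) {
  set.seed(seed)
  m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  if (sum(m) == 0) m[nr %/% 2, nc %/% 2] <- 1L
  raster_trace(m, specimen_id = paste0("rand", seed))
}
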