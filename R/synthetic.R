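#' Generate a rasterized curve of known fractal dimension
#'
#' Deterministic geometric fixtures for the box-counting estimator:
#' polylines are constructed exactly (L-system / complex-arithmetic
#' expansion) and rasterized to a one-pixel-wide binary path with
#' integer (Bresenham) line drawing, no anti-aliasing, so the output is
#' truly binary. Available kinds and their analytic dimensions:
#' \describe{
#'   \item{line}{straight line at \code{angle} degrees; D = 1}
#'   \item{filled_box}{fully filled raster; D = 2 (use
#'     \code{estimate_D(border = FALSE)} on it)}
#'   \item{koch}{triadic Koch curve; D = log 4 / log 3 ~ 1.2619}
#'   \item{quadric_koch}{8-segment quadric Koch (Minkowski sausage);
#'     D = log 8 / log 4 = 1.5}
#'   \item{sierpinski}{Sierpinski arrowhead curve; D = log 3 / log 2
#'     ~ 1.585}
#' }
#'
#' @param kind one of \code{"line"}, \code{"filled_box"}, \code{"koch"},
#'   \code{"quadric_koch"}, \code{"sierpinski"}.
#' @param iterations construction depth for the fractal kinds.
#' @param raster_px output raster width in pixels (>= 64); the raster is
#'   square.
#' @param angle line orientation in degrees (line kind only).
#' @return list with \code{trace} (a [raster_trace()]) and
#'   \code{analytic_D}.
#' @export
generate_curve <- function(kind = c("line", "filled_box", "koch",
                                    "quadric_koch", "sierpinski"),
                           iterations = 5L, raster_px = 729L, angle = 0) {
  kind <- match.arg(kind)
  raster_px <- as.integer(raster_px)
  if (raster_px < 64L) stop("'raster_px' must be >= 64")
  if (iterations < 0L) stop("'iterations' must be >= 0")
  if (kind == "filled_box") {
    return(list(trace = raster_trace(matrix(1L, raster_px, raster_px),
                                     specimen_id = "filled_box"),
                analytic_D = 2))
  }
  shrink <- switch(kind, line = 1, koch = 3, quadric_koch = 4,
                   sierpinski = 2)
  if (kind != "line" && raster_px / shrink^iterations < 1)
    stop("raster too small to resolve iteration depth ", iterations)
  pts <- switch(kind,
    line = {
      a <- angle * pi / 180
      complex(real = c(0, cos(a)), imaginary = c(0, sin(a)))
    },
    koch = koch_points(iterations),
    quadric_koch = turtle_points(
      lsystem("F", c(F = "F+F-F-FF+F+F-F"), iterations), 90),
    sierpinski = turtle_points(
      lsystem("A", c(A = "B-A-B", B = "A+B+A"), iterations), 60))
  D <- switch(kind, line = 1, koch = log(4) / log(3),
              quadric_koch = 1.5, sierpinski = log(3) / log(2))
  list(trace = raster_trace(rasterize_polyline(pts, raster_px),
                            specimen_id = kind),
       analytic_D = D)
}

# triadic Koch curve by complex-segment expansion
koch_points <- function(iterations) {
  pts <- complex(real = c(0, 1), imaginary = c(0, 0))
  rot <- exp(-1i * pi / 3)   # bump below the baseline (image rows grow down)
  for (k in seq_len(iterations)) {
    a <- pts[-length(pts)]; b <- pts[-1]
    d <- (b - a) / 3
    seg <- rbind(a, a + d, a + d + d * rot, a + 2 * d)
    pts <- c(as.vector(seg), pts[length(pts)])
  }
  pts
}

# iterated string rewriting
lsystem <- function(axiom, rules, iterations) {
  s <- strsplit(axiom, "")[[1]]
  for (k in seq_len(iterations)) {
    s <- unlist(lapply(s, function(ch) {
      if (ch %in% names(rules)) strsplit(rules[[ch]], "")[[1]] else ch
    }), use.names = FALSE)
  }
  s
}

# turtle interpretation: letters draw a unit step, +/- turn by angle_deg
turtle_points <- function(symbols, angle_deg) {
  turn <- exp(1i * angle_deg * pi / 180)
  pos <- 0 + 0i; head <- 1 + 0i
  pts <- pos
  for (ch in symbols) {
    if (ch == "+") head <- head * turn
    else if (ch == "-") head <- head / turn
    else { pos <- pos + head; pts <- c(pts, pos) }
  }
  pts
}

# scale a complex polyline into a px-by-px grid and draw with Bresenham
rasterize_polyline <- function(pts, px) {
  x <- Re(pts); y <- Im(pts)
  rx <- diff(range(x)); ry <- diff(range(y))
  scale <- (px - 1) / max(rx, ry, .Machine$double.eps)
  cc <- round((x - min(x)) * scale) + 1L
  rr <- round((y - min(y)) * scale) + 1L
  m <- matrix(0L, px, px)
  for (i in seq_len(length(pts) - 1L)) {
    seg <- bresenham(rr[i], cc[i], rr[i + 1L], cc[i + 1L])
    m[seg] <- 1L
  }
  m
}

# integer line rasterization; returns a 2-column (row, col) index matrix
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from one lineage at time 0, each of the
#' k current lineages splits at rate \code{birth}, so waiting times are
#' exponential with rate k * birth and the splitting lineage is chosen
#' uniformly. Once \code{n_tips} lineages exist the simulation runs on
#' to the moment the next split would occur and stops there, so every
#' terminal branch has positive length; all tips end at that moment
#' (the tree is ultrametric). The expected root-to-tip depth is
#' H(n) / birth, with H the harmonic number. Reproducible under
#' \code{seed}.
#'
#' @param n_tips number of tips, >= 3.
#' @param birth per-lineage speciation rate, > 0.
#' @param seed optional integer seed.
#' @return an \code{ape::phylo} with tip labels \code{t1..tn}.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = NULL) {
  if (n_tips < 3L) stop("'n_tips' must be >= 3")
  if (birth <= 0) stop("'birth' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  parent <- 0L; birth_time <- 0
  active <- 1L; t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = birth * k)
    split <- active[sample.int(k, 1L)]
    id <- length(parent) + c(1L, 2L)
    parent[id] <- split
    birth_time[id] <- t
    active <- c(active[active != split], id)
  }
  # sample the present at the time of the would-be next split, so the
  # final cherry does not collapse to zero-length terminal branches
  t <- t + stats::rexp(1, rate = birth * n_tips)
  nlin <- length(parent)
  end_time <- numeric(nlin)
  end_time[active] <- t
  internals <- setdiff(seq_len(nlin), active)
  for (v in internals) end_time[v] <- birth_time[parent == v][1]
  # renumber to ape convention: tips 1..n, internals n+1..2n-1, root n+1
  map <- integer(nlin)
  map[sort(active)] <- seq_len(n_tips)
  map[sort(internals)] <- n_tips + seq_along(internals)
  children <- which(parent > 0L)
  tree <- structure(list(
    edge = cbind(map[parent[children]], map[children]),
    edge.length = end_time[children] - birth_time[children],
    tip.label = paste0("t", seq_len(n_tips)),
    Nnode = n_tips - 1L), class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate species traits with lambda-structured residuals
#'
#' The generating model assumed by the phylogenetic regression: the
#' predictor x (occlusal area, cm^2) is drawn independently per tip,
#' and y = intercept + slope * x + e with e multivariate normal,
#' covariance sigma2 * lambda-transform of the tree's Brownian
#' covariance. lambda = 1 gives fully Brownian residuals, lambda = 0
#' independent residuals with variance proportional to tip depth.
#'
#' @param tree a dated \code{phylo}.
#' @param lambda Pagel's lambda of the residuals, in [0, 1].
#' @param slope,intercept regression coefficients (defaults mirror a
#'   shallow negative complexity-area relationship, D ~ 1.45 - 0.016 x).
#' @param sigma2 Brownian rate (trait variance per Ma), > 0.
#' @param seed optional integer seed.
#' @param x_mean,x_sd normal parameters for the predictor draw
#'   (defaults resemble occlusal areas of 2-9 cm^2).
#' @return data.frame with columns \code{taxon}, \code{x}, \code{y}.
#' @export
simulate_traits <- function(tree, lambda = 1, slope = -0.016,
                            intercept = 1.45, sigma2 = 1e-4, seed = NULL,
                            x_mean = 5, x_sd = 1.5) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  V <- phylo_covariance(tree)
  n <- nrow(V)
  S <- sigma2 * lambda_transform(V, lambda)
  x <- stats::rnorm(n, x_mean, x_sd)
  e <- as.numeric(t(chol(S)) %*% stats::rnorm(n))
  data.frame(taxon = rownames(V), x = x, y = intercept + slope * x + e,
             stringsAsFactors = FALSE)
}

#' Simulate a full specimen cohort with known ground truth
#'
#' Builds everything the end-to-end pipeline consumes: a pure-birth
#' tree, species-mean traits from [simulate_traits()], and a specimen
#' table in which each species contributes 1-6 specimens whose D values
#' scatter around the species mean with Gaussian within-species noise
#' (default SD 0.05, the typical within-species dispersion of published
#' equid D measurements). Tribes are assigned by the root split of the
#' tree, mimicking two sister clades.
#'
#' @param n_species number of species (tree tips).
#' @param lambda,slope,intercept,sigma2 passed to [simulate_traits()].
#' @param specimen_sd within-species SD of specimen D values.
#' @param birth pure-birth rate for the tree.
#' @param seed integer seed governing every draw.
#' @return list with \code{tree}, \code{species} (taxon, tribe, x, y),
#'   \code{specimens} (specimen_id, taxon, tribe, tooth_position, area,
#'   D), and \code{params}.
#' @export
simulate_cohort <- function(n_species = 35L, lambda = 0, slope = -0.016,
                            intercept = 1.45, sigma2 = 1e-4,
                            specimen_sd = 0.05, birth = 0.25,
                            seed = 1L) {
  set.seed(seed)
  tree <- simulate_tree(n_species, birth = birth)
  species <- simulate_traits(tree, lambda = lambda, slope = slope,
                             intercept = intercept, sigma2 = sigma2)
  # two "tribes" = the two daughter clades of the root
  root_kids <- tree$edge[tree$edge[, 1] == n_species + 1L, 2]
  clade1 <- if (root_kids[1] <= n_species) tree$tip.label[root_kids[1]]
            else ape::extract.clade(tree, root_kids[1])$tip.label
  species$tribe <- ifelse(species$taxon %in% clade1,
                          "Hipparionini", "Equini")
  n_spec <- sample(1:6, n_species, replace = TRUE)
  specimens <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    k <- n_spec[i]
    data.frame(
      specimen_id = sprintf("%s_s%d", gsub(" ", "_", species$taxon[i]),
                            seq_len(k)),
      taxon = species$taxon[i], tribe = species$tribe[i],
      tooth_position = sample(c("P3", "P4", "M1", "M2"), k, replace = TRUE,
                              prob = c(0.6, 0.2, 0.1, 0.1)),
      area = pmax(0.5, stats::rnorm(k, species$x[i], 0.4)),
      D = stats::rnorm(k, species$y[i], specimen_sd),
      stringsAsFactors = FALSE)
  }))
  rownames(specimens) <- NULL
  list(tree = tree, species = species, specimens = specimens,
       params = list(n_species = n_species, lambda = lambda, slope = slope,
                     intercept = intercept, sigma2 = sigma2,
                     specimen_sd = specimen_sd, birth = birth, seed = seed))
}

#' Published species-level summary of equid enamel complexity
#'
#' The packaged species table of fractal dimension (D) and occlusal
#' surface area for 35 Hipparionini and Equini species (98 specimens):
#' per-species specimen counts, means and sample SDs as printed in the
#' published summary, with NA where a species has a single specimen
#' (no SD) or no area measurement. Used for summary-level
#' reconstructions (tribe pooling, Welch t-test) without raw images.
#'
#' @return data.frame with columns \code{tribe}, \code{taxon},
#'   \code{n_D}, \code{mean_D}, \code{sd_D}, \code{n_area},
#'   \code{mean_area}, \code{sd_area}.
#' @export
equid_species_summary <- function() {
  path <- system.file("extdata", "equid_species_summary.csv",
                      package = "enamelD", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
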