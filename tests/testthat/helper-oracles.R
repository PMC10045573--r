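# Independent oracles used across tests.  These deliberately avoid the
# package's production code paths.

# Geodesic distances by igraph shortest paths over the explicit pixel graph.
oracle_geodesic_2d <- function(values, seeds, connectivity = 8) {
  d <- dim(values)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  if (connectivity == 4) off <- off[abs(off$dr) + abs(off$dc) == 1, ]
  coords <- as.matrix(expand.grid(r = seq_len(d[1]), c = seq_len(d[2])))
  lin <- function(cc) (cc[, 1] - 1) + (cc[, 2] - 1) * d[1] + 1
  ef <- integer(0); et <- integer(0); w <- numeric(0)
  for (i in seq_len(nrow(off))) {
    nb <- cbind(coords[, 1] + off$dr[i], coords[, 2] + off$dc[i])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
    ef <- c(ef, lin(coords[ok, , drop = FALSE]))
    et <- c(et, lin(nb[ok, , drop = FALSE]))
    w <- c(w, abs(values[coords[ok, , drop = FALSE]] -
                    values[nb[ok, , drop = FALSE]]))
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = TRUE)
  dm <- igraph::distances(g, v = lin(seeds), mode = "out", weights = w)
  array(apply(dm, 2, min), dim = d)
}

# Exhaustive global minimum of the CRF energy on a tiny grid.
oracle_crf_minimum <- function(R, img, clicks, params) {
  d <- dim(if (inherits(img, "intensity_image")) img$values else img)
  n <- prod(d)
  stopifnot(n <= 12)
  in_clicks <- function(m, lab, want) {
    if (is.null(m)) return(TRUE)
    all(vapply(seq_len(nrow(m)), function(i) {
      lab[m[i, , drop = FALSE]] == want
    }, logical(1)))
  }
  best <- Inf
  for (code in 0:(2^n - 1)) {
    y <- as.integer(intToBits(code)[1:n])
    lab <- binary_mask(array(y, dim = d))
    if (!in_clicks(clicks$fg, lab, 1L) || !in_clicks(clicks$bg, lab, 0L)) {
      next
    }
    e <- crf_energy(lab, R, img, clicks, params)
    best <- min(best, e)
  }
  best
}

# Shared seeded phantom-suite runner: initial phase plus oracle-click
# refinement rounds; returns the per-phantom DSC trajectories.
run_phantom_suite <- function(seeds, rounds = 3, spec_args = list()) {
  lapply(seeds, function(s) {
    spec <- do.call(phantom_spec, c(list(seed = s), spec_args))
    ph <- generate_phantom(spec)
    target <- sample(seq_len(max(ph$tumour_labels)), 1)
    gt <- binary_mask(ph$tumour_labels == target)
    clicks <- simulate_inner_margin_points(gt, n_extra = 5, seed = s * 7)
    sess <- run_initial(ph$image, clicks)
    tr <- dice(gt, session_mask(sess))
    for (r in seq_len(rounds)) {
      cc <- simulate_correction_clicks(session_mask(sess), gt)
      sess <- run_refine(sess, cc)
      tr <- c(tr, dice(gt, session_mask(sess)))
    }
    tr
  })
}

# Small random star-convex blob mask for interaction property tests.
random_blob_mask <- function(shape = c(48, 48), seed = 1) {
  set.seed(seed)
  ctr <- shape / 2 + runif(2, -5, 5)
  r0 <- runif(1, 6, min(shape) / 3)
  a <- runif(3, 0, 0.12)
  ph <- runif(3, 0, 2 * pi)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  t <- atan2(rr - ctr[1], cc - ctr[2])
  rad <- r0 * (1 + a[1] * cos(2 * t + ph[1]) + a[2] * cos(3 * t + ph[2]) +
                 a[3] * cos(5 * t + ph[3]))
  binary_mask(sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) <= rad)
}
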