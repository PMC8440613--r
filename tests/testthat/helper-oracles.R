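# Independent oracles used across the suite.  Each deliberately reimplements
# the quantity it checks by the most naive route available (per-pixel loops,
# exhaustive vertex enumeration, closed forms) so it shares no code with the
# implementation under test.

# one shared category table; loading is idempotent so sharing is safe
iscc_tab <- loadIsccTable()

# naive triple-loop histogram: counts pixels per (rR, rG, rB) region
oracle_bin_proportions <- function(px, k) {
  w <- 256 / k
  counts <- array(0L, dim = c(k, k, k))
  for (p in seq_len(nrow(px))) {
    i <- min(floor(px[p, 1] / w) + 1, k)
    j <- min(floor(px[p, 2] / w) + 1, k)
    l <- min(floor(px[p, 3] / w) + 1, k)
    counts[i, j, l] <- counts[i, j, l] + 1L
  }
  counts / nrow(px)
}

# exact transportation optimum by enumerating all basis subsets of
# m + n - 1 cells (vertices of the transportation polytope); feasible for
# signatures of up to ~4x4 bins
oracle_transport_cost <- function(cost, supply, demand) {
  m <- length(supply)
  n <- length(demand)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  nb <- m + n - 1
  best <- Inf
  for (sel in combn(nrow(cells), nb, simplify = FALSE)) {
    A <- matrix(0, m + n - 1, nb)
    for (c_ in seq_len(nb)) {
      i <- cells$i[sel[c_]]
      j <- cells$j[sel[c_]]
      A[i, c_] <- 1                       # row-sum constraints
      if (j < n) A[m + j, c_] <- A[m + j, c_] + 1  # col sums, last dropped
    }
    if (qr(A)$rank < nb) next
    f <- tryCatch(solve(A, c(supply, demand[-n])), error = function(e) NULL)
    if (is.null(f) || any(f < -1e-9)) next
    cc <- sum(f * cost[cbind(cells$i[sel], cells$j[sel])])
    if (cc < best) best <- cc
  }
  best
}

# closed-form OLS via the normal equations
oracle_ols <- function(X, y) drop(solve(t(X) %*% X) %*% t(X) %*% y)

# step-by-step transcription of the Hedges' d formulas
oracle_hedges <- function(mt, st, nt, mc, sc, nc) {
  m <- nt + nc - 2
  sp <- sqrt(((nt - 1) * st^2 + (nc - 1) * sc^2) / m)
  j <- 1 - 3 / (4 * m - 1)
  d <- j * (mt - mc) / sp
  list(d = d, variance = (nt + nc) / (nt * nc) + d^2 / (2 * (nt + nc)))
}

# random valid comparison records
random_comparisons <- function(n, seed, classes = c("richness", "abundance",
                                                    "recruitment"),
                               nMin = 2, nMax = 40, meanMax = 50) {
  set.seed(seed)
  data.frame(
    study_id = sprintf("s%02d", sample(8, n, replace = TRUE)),
    response_class = sample(classes, n, replace = TRUE),
    family = NA_character_,
    mean_treat = runif(n, 0, meanMax), sd_treat = runif(n, 0.5, 5),
    n_treat = sample(nMin:nMax, n, replace = TRUE),
    mean_ctrl = runif(n, 0, meanMax), sd_ctrl = runif(n, 0.5, 5),
    n_ctrl = sample(nMin:nMax, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# random mass-1 colour signature
random_signature <- function(nbins, id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- runif(nbins) + 0.05
  new("ColourSignature", reefId = id,
      bins = data.frame(r = runif(nbins, 0, 255), g = runif(nbins, 0, 255),
                        b = runif(nbins, 0, 255), weight = w / sum(w)))
}
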